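# Genetic-code tables and MG94xREV parameter plumbing. The universal code's
# 61 sense codons are the state space throughout; the single-nucleotide
# change table drives both the generator construction (C++) and the
# synonymous/non-synonymous bookkeeping.

NUC <- c("A", "C", "G", "T")

# unordered nucleotide pair index, GTR order: AC AG AT CG CT GT
NT_PAIR <- matrix(0L, 4, 4, dimnames = list(NUC, NUC))
NT_PAIR["A", "C"] <- NT_PAIR["C", "A"] <- 1L
NT_PAIR["A", "G"] <- NT_PAIR["G", "A"] <- 2L
NT_PAIR["A", "T"] <- NT_PAIR["T", "A"] <- 3L
NT_PAIR["C", "G"] <- NT_PAIR["G", "C"] <- 4L
NT_PAIR["C", "T"] <- NT_PAIR["T", "C"] <- 5L
NT_PAIR["G", "T"] <- NT_PAIR["T", "G"] <- 6L

genetic_code_tables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- Biostrings::GENETIC_CODE
    sense <- names(gc)[gc != "*"]
    aa <- unname(gc[sense])
    splits <- do.call(rbind, strsplit(sense, ""))
    nt_idx <- matrix(match(splits, NUC), ncol = 3)
    # ordered single-nucleotide codon changes
    rows <- list()
    n <- length(sense)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        diffp <- which(splits[i, ] != splits[j, ])
        if (length(diffp) != 1L) next
        p <- diffp
        rows[[length(rows) + 1L]] <- c(
          i - 1L, j - 1L,
          NT_PAIR[splits[i, p], splits[j, p]] - 1L,
          p - 1L,
          match(splits[j, p], NUC) - 1L,
          as.integer(aa[i] == aa[j])
        )
      }
    }
    changes <- do.call(rbind, rows)
    storage.mode(changes) <- "integer"
    cache <<- list(codons = sense, aa = aa, nt_idx = nt_idx, changes = changes)
    cache
  }
})

#' F3x4 codon equilibrium frequencies
#'
#' Position-specific nucleotide frequencies are estimated from the alignment
#' and multiplied across the three codon positions; stop codons are excluded
#' and the vector renormalized. Zero-frequency nucleotides are floored at
#' 1e-6 before renormalizing so the generator stays irreducible.
#'
#' @param aln A [codon_alignment()].
#' @return Numeric vector of length 61 (named by codon, summing to 1) with
#'   attribute `"pinuc"`, the 3 x 4 position-specific nucleotide frequencies.
#' @export
codon_frequencies_f3x4 <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  gct <- genetic_code_tables()
  states <- aln$states
  obs <- states[!is.na(states)]
  pinuc <- matrix(0, 3, 4, dimnames = list(NULL, NUC))
  for (p in 1:3) {
    tab <- tabulate(gct$nt_idx[obs, p], nbins = 4)
    f <- tab / sum(tab)
    f <- pmax(f, 1e-6)
    pinuc[p, ] <- f / sum(f)
  }
  pi61 <- pinuc[1, gct$nt_idx[, 1]] * pinuc[2, gct$nt_idx[, 2]] *
    pinuc[3, gct$nt_idx[, 3]]
  pi61 <- pi61 / sum(pi61)
  names(pi61) <- gct$codons
  attr(pi61, "pinuc") <- pinuc
  pi61
}

#' MG94xREV model parameters
#'
#' Bundles the GTR exchangeabilities (6 values in AC, AG, AT, CG, CT, GT
#' order; AG is the reference and should be 1) with F3x4 frequencies.
#'
#' @param rho Numeric vector of 6 GTR exchangeabilities.
#' @param pi F3x4 codon frequencies as from [codon_frequencies_f3x4()], or a
#'   3 x 4 position-specific nucleotide frequency matrix.
#' @return An object of class `mg94_params`.
#' @export
mg94_params <- function(rho = c(1, 1, 1, 1, 1, 1), pi = NULL) {
  stopifnot(length(rho) == 6, all(rho > 0))
  gct <- genetic_code_tables()
  if (is.null(pi)) pi <- uniform_f3x4()
  if (is.matrix(pi)) {
    pinuc <- pi
    pi <- pinuc[1, gct$nt_idx[, 1]] * pinuc[2, gct$nt_idx[, 2]] *
      pinuc[3, gct$nt_idx[, 3]]
    pi <- pi / sum(pi)
    names(pi) <- gct$codons
  } else {
    stopifnot(length(pi) == 61)
    pinuc <- attr(pi, "pinuc")
    if (is.null(pinuc)) stop("pi must carry its 'pinuc' attribute", call. = FALSE)
  }
  structure(list(rho = as.numeric(rho), pi = as.numeric(pi), pinuc = pinuc,
                 codons = gct$codons),
            class = "mg94_params")
}

uniform_f3x4 <- function() {
  gct <- genetic_code_tables()
  pinuc <- matrix(0.25, 3, 4, dimnames = list(NULL, NUC))
  pi <- rep(1, 61)
  pi <- pi / 61  # uniform nucleotide usage -> uniform over the 61 sense codons
  names(pi) <- gct$codons
  attr(pi, "pinuc") <- pinuc
  pi
}

#' MG94xREV rate and transition matrices
#'
#' Builds the 61 x 61 generator for given synonymous (`s`) and
#' non-synonymous (`n`) branch rates, and the transition matrix
#' `P = expm(Q * t)`. Only codon pairs differing at a single nucleotide have
#' nonzero rate; the factor is the GTR exchangeability of the nucleotide pair
#' times the position-specific frequency of the target nucleotide, times `s`
#' or `n`.
#'
#' @param params An [mg94_params()] object.
#' @param s,n Synonymous and non-synonymous rates (>= 0).
#' @param t Time/scale multiplier for the transition matrix.
#' @return List with `Q` (rows sum to 0) and `P` (rows sum to 1), both with
#'   codon dimnames.
#' @export
mg94_q_and_p <- function(params, s, n, t = 1) {
  stopifnot(inherits(params, "mg94_params"), s >= 0, n >= 0, t >= 0)
  gct <- genetic_code_tables()
  Q <- mg94_q_cpp(gct$changes, params$rho, params$pinuc, s, n)
  P <- mg94_pmat_cpp(gct$changes, params$rho, params$pinuc, params$pi,
                     s * t, n * t)
  dimnames(Q) <- dimnames(P) <- list(gct$codons, gct$codons)
  list(Q = Q, P = P)
}

#' In-frame codon alignment container
#'
#' Accepts a named character vector of DNA sequences, a path to a FASTA file,
#' or a `DNAStringSet`. Sequences must share a length divisible by 3; codons
#' containing anything outside ACGT are treated as missing; observed stop
#' codons are an error.
#'
#' @param x Sequences (see above).
#' @return Object of class `codon_alignment`: list with `states` (integer
#'   matrix species x codons, 1..61 or NA), `species`, `ncodons`.
#' @export
codon_alignment <- function(x) {
  if (inherits(x, "codon_alignment")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      !grepl("^[ACGTNacgtn-]+$", x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (inherits(x, "DNAStringSet")) x <- setNames(as.character(x), names(x))
  stopifnot(is.character(x), !is.null(names(x)))
  names(x) <- normalize_species(names(x))
  if (anyDuplicated(names(x))) stop("duplicate sequence names", call. = FALSE)
  lens <- nchar(x)
  if (length(unique(lens)) != 1L) stop("sequences have unequal lengths",
                                       call. = FALSE)
  if (lens[1] %% 3 != 0) stop("alignment length not a multiple of 3",
                              call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 sequences", call. = FALSE)
  gct <- genetic_code_tables()
  nc <- lens[1] %/% 3
  states <- matrix(NA_integer_, length(x), nc,
                   dimnames = list(names(x), NULL))
  for (k in seq_along(x)) {
    cod <- substring(toupper(x[k]), 3 * seq_len(nc) - 2, 3 * seq_len(nc))
    idx <- match(cod, gct$codons)
    stopcod <- !is.na(match(cod, c("TAA", "TAG", "TGA")))
    if (any(stopcod))
      stop("stop codon observed in ", names(x)[k], " at codon ",
           which(stopcod)[1], call. = FALSE)
    states[k, ] <- idx
  }
  structure(list(states = states, species = names(x), ncodons = nc),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", length(x$species), " sequences x ", x$ncodons,
      " codons\n", sep = "")
  invisible(x)
}

#' Write a codon alignment to FASTA
#'
#' @param aln A [codon_alignment()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_codon_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  gct <- genetic_code_tables()
  seqs <- apply(aln$states, 1, function(row) {
    cod <- ifelse(is.na(row), "NNN", gct$codons[row])
    paste(cod, collapse = "")
  })
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seqs, aln$species)), path)
  invisible(path)
}

# pruning preliminaries shared by likelihood, fitting and simulation
codon_prep <- function(aln, tree) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(tree, "phylo"))
  missing_in_aln <- setdiff(tree$tip.label, aln$species)
  if (length(missing_in_aln))
    stop("tree tips absent from alignment: ",
         paste(head(missing_in_aln, 5), collapse = ", "), call. = FALSE)
  ntip <- ape::Ntip(tree)
  ord <- postorder_edges(tree)
  edges <- tree$edge[ord, , drop = FALSE]
  states <- aln$states[match(tree$tip.label, aln$species), , drop = FALSE]
  # pattern compression
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pat <- states[, first, drop = FALSE]
  w <- as.numeric(table(factor(key, levels = key[first])))
  pat0 <- pat
  pat0[is.na(pat0)] <- 0L
  pat0 <- pat0 - 1L  # 0-based, -1 missing
  list(patterns = pat0, weights = w, edges0 = edges - 1L,
       edge_order = ord, nnode = ntip + tree$Nnode, root0 = ntip,
       ntip = ntip, nsites = aln$ncodons)
}

#' Felsenstein pruning log-likelihood of a codon alignment
#'
#' Computes the MG94xREV log-likelihood over the 61 sense codons with the
#' stationary distribution placed at an arbitrary virtual root (the result is
#' root-placement invariant because the model is reversible). Gaps and
#' ambiguous codons contribute a partial likelihood of 1.
#'
#' @param aln A [codon_alignment()].
#' @param tree A `phylo` whose tips are all present in `aln` (typically
#'   unrooted for fitting).
#' @param params An [mg94_params()] object.
#' @param rates Data frame with columns `dS`, `dN` (one row per edge, in
#'   `tree$edge` order), or a list with numeric vectors `dS`, `dN`.
#' @return Log-likelihood (scalar).
#' @export
pruning_loglik <- function(aln, tree, params, rates) {
  prep <- codon_prep(codon_alignment(aln), tree)
  E <- nrow(tree$edge)
  dS <- rates$dS
  dN <- rates$dN
  stopifnot(length(dS) == E, length(dN) == E, all(dS >= 0), all(dN >= 0))
  gct <- genetic_code_tables()
  Pc <- mg94_pmats_cpp(gct$changes, params$rho, params$pinuc, params$pi,
                       dS[prep$edge_order], dN[prep$edge_order])
  prune_loglik_cpp(prep$patterns, prep$weights, prep$edges0, Pc,
                   params$pi, prep$nnode, prep$root0)
}
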