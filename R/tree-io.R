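#' Read a phylogeny from Newick text or file
#'
#' Thin, validating wrapper around [ape::read.tree()]. Tip labels are
#' normalized by replacing spaces with underscores so that trait tables and
#' sequence headers written under different conventions match. Edges without a
#' branch length default to 0.
#'
#' @param x A Newick string, or the path to a file containing one.
#' @return An object of class `phylo`.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (file.exists(x) && !grepl("\\(", x)) paste(readLines(x), collapse = "") else x
  if (!grepl("\\(", txt) || !grepl(";", txt)) {
    stop("not a Newick string (no parentheses/terminating ';'): ",
         substr(txt, 1, 40), call. = FALSE)
  }
  if (lengths(regmatches(txt, gregexpr("\\(", txt))) !=
      lengths(regmatches(txt, gregexpr("\\)", txt)))) {
    stop("malformed Newick: unbalanced parentheses", call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e),
                                          call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: ape returned NULL", call. = FALSE)
  tr$tip.label <- normalize_species(tr$tip.label)
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) {
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (any(tr$edge.length < 0)) stop("negative branch length(s)", call. = FALSE)
  tr
}

#' Write a phylogeny as Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

normalize_species <- function(x) gsub("[ ]+", "_", trimws(x))

genus_of <- function(x) sub("_.*$", "", x)

#' Match species names to tree tips and prune
#'
#' Exact matches are taken first (after normalizing spaces to underscores).
#' With `genus_fallback`, an unmatched name may bind to a tip of the same
#' genus, but only when exactly one unclaimed congeneric tip exists; an
#' ambiguous genus is recorded as unmatched, never guessed. Matched tips are
#' relabelled with the query name so downstream joins use the query's
#' spelling.
#'
#' @param tree A `phylo` object.
#' @param names Character vector of species names to retain.
#' @param genus_fallback Allow unambiguous single-congener matches.
#' @return A list with `tree` (pruned, relabelled) and `report`, a tibble with
#'   columns `query`, `tip`, `match` (one of `"exact"`, `"genus"`,
#'   `"unmatched"`).
#' @export
match_and_prune <- function(tree, names, genus_fallback = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (!length(names)) stop("no species names supplied", call. = FALSE)
  q <- normalize_species(names)
  tips <- tree$tip.label
  rep_tbl <- tibble::tibble(query = q, tip = NA_character_,
                            match = "unmatched")
  exact <- match(q, tips)
  rep_tbl$tip[!is.na(exact)] <- tips[exact[!is.na(exact)]]
  rep_tbl$match[!is.na(exact)] <- "exact"
  if (genus_fallback) {
    claimed <- rep_tbl$tip[!is.na(rep_tbl$tip)]
    for (k in which(rep_tbl$match == "unmatched")) {
      g <- genus_of(rep_tbl$query[k])
      cand <- setdiff(tips[genus_of(tips) == g], claimed)
      if (length(cand) == 1L) {
        rep_tbl$tip[k] <- cand
        rep_tbl$match[k] <- "genus"
        claimed <- c(claimed, cand)
      }
    }
  }
  hit <- !is.na(rep_tbl$tip)
  if (!any(hit)) stop("no query species matched any tree tip", call. = FALSE)
  keep <- rep_tbl$tip[hit]
  pruned <- ape::keep.tip(tree, keep)
  idx <- match(pruned$tip.label, rep_tbl$tip)
  pruned$tip.label <- rep_tbl$query[idx]
  list(tree = pruned, report = rep_tbl)
}

#' Read a species trait table
#'
#' Expects a TSV with header columns `species`, `testes_mass_g`,
#' `body_mass_g`, `clade` (masses in raw grams). Masses are log10-transformed
#' on load, exactly once.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `species`, `testes_mass_log10`,
#'   `body_mass_log10`, `clade`.
#' @export
read_trait_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "testes_mass_g", "body_mass_g", "clade")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trait table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out <- tibble::tibble(
    species = normalize_species(df$species),
    testes_mass_log10 = log10(df$testes_mass_g),
    body_mass_log10 = log10(df$body_mass_g),
    clade = as.character(df$clade)
  )
  validate_trait_table(out)
}

#' Write a trait table back to disk in raw grams
#'
#' @param traits Tibble as returned by [read_trait_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  validate_trait_table(traits)
  df <- data.frame(
    species = traits$species,
    testes_mass_g = 10^traits$testes_mass_log10,
    body_mass_g = 10^traits$body_mass_log10,
    clade = traits$clade
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_trait_table <- function(traits) {
  stopifnot(is.data.frame(traits))
  need <- c("species", "testes_mass_log10", "body_mass_log10", "clade")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop("trait table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(traits$species))
    stop("duplicate species in trait table", call. = FALSE)
  if (!all(is.finite(traits$testes_mass_log10)) ||
      !all(is.finite(traits$body_mass_log10)))
    stop("non-finite mass value(s) in trait table", call. = FALSE)
  tibble::as_tibble(traits)
}
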