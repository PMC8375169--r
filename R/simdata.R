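# Rate-coupled simulator of trees, trait tables and codon alignments.
# The generator emulates the study design end to end: a time-calibrated
# tree, clade-specific testes/body allometries whose phylogenetic residual
# evolves under Brownian motion with branch-specific rate scalars, and
# MG94xREV codon alignments whose per-branch non-synonymous rates can be
# coupled (positively or negatively) to the phenotypically fast branches,
# or directionally to the residual increments themselves.

#' Simulation scenario
#'
#' Bundles every knob of the synthetic benchmark. Defaults describe the
#' desk-scale study conditions: 64 taxa, 300 Myr deep pure-birth tree, five
#' clades with their own testes/body allometries, a background residual
#' Brownian rate of 0.001 log10-g^2/Myr with a rate burst on a quarter of
#' the terminal branches, and 300-codon MG94xREV alignments at omega = 0.2
#' with log-normal branch-rate jitter.
#'
#' @param n_taxa Number of ingroup tips.
#' @param depth Tree depth in Myr.
#' @param clades Tibble with columns `label`, `intercept`, `slope`: the
#'   clade-specific allometries of log10 testes mass on log10 body mass.
#' @param bm_root,bm_sigma2 Root value and Brownian rate of log10 body mass.
#' @param sigma2_b Background Brownian rate of the testes-mass residual
#'   (log10-g^2 per Myr).
#' @param r_scalar Rate scalar applied to the fast-branch set (1 = none).
#' @param fast_set How the phenotypically fast branches are chosen:
#'   `"tips"` (the default) draws each terminal branch independently with
#'   probability `fast_prob` — many phylogenetically unconfounded bursts,
#'   each individually detectable, the benchmark's standard condition;
#'   `"clade"` scales every branch within `fast_clade` (a single clade-wide
#'   burst, the x16 recovery scenario); `"subclades"` scales all branches of
#'   `fast_nclades` disjoint mid-sized subtrees; `"scattered"` draws every
#'   branch (terminal or internal) independently.
#' @param fast_nclades Number of burst subtrees under `"subclades"`.
#' @param fast_prob Per-branch probability of being fast under `"tips"`
#'   and `"scattered"`.
#' @param fast_clade Label of the clade whose branches are phenotypically
#'   fast under `"clade"`.
#' @param ncodons Codon alignment length.
#' @param rho GTR exchangeabilities (AC, AG, AT, CG, CT, GT; AG = 1).
#' @param pinuc 3 x 4 position-specific nucleotide frequencies.
#' @param alpha Synonymous rate per Myr (branch dS = alpha * t).
#' @param omega Baseline dN/dS ratio (branch dN = omega * alpha * t).
#' @param branch_rate_sd Log-normal standard deviation of random per-branch
#'   rate heterogeneity, applied independently to every branch's synonymous
#'   and non-synonymous rate. This reproduces the ubiquitous
#'   branch-to-branch molecular rate variation seen even in genes with no
#'   phenotype association (control genes); set to 0 for strictly
#'   global-model data.
#' @param coupling Set-based rate-coupling strength c >= 0: non-synonymous
#'   rates on the coupled branch set are multiplied by (1 + c).
#' @param coupling_target `"fast"` couples the phenotypically fast branches
#'   (driver genes), `"slow"` the complementary set (moderator genes).
#' @param rate_coupling Realized-rate coupling strength: terminal branches
#'   are classed as realized-fast when their squared standardized trait
#'   increment `w_b` (realized phenotypic speed relative to the background
#'   rate) exceeds `realized_threshold`. With `rate_coupling = c > 0`,
#'   non-synonymous rates on realized-fast terminals are multiplied by
#'   `1 + c` — protein change tracks the lineages where the phenotype
#'   actually changed fast (drivers). With `c < 0` the multiplier `1 + |c|`
#'   is applied to the realized-slow terminals instead — protein change
#'   concentrates where the phenotype stagnated (moderators). This is the
#'   benchmark's primary coupling: it ties the gene to the same realized
#'   rate signal the variable-rates model estimates.
#' @param realized_threshold Realized-speed cutoff separating fast from
#'   slow terminals (9, roughly a 3-sigma excursion: ordinary branches
#'   exceed it with probability 0.003).
#' @param gamma Directional coupling: per-branch non-synonymous rates are
#'   multiplied by `exp(gamma * z_b)` where `z_b` is the standardized
#'   Brownian increment of the testes residual on that branch, so root-to-tip
#'   dN tracks the final trait value.
#' @param outgroup,outgroup_stem Outgroup tip label and extra stem depth
#'   (Myr) for codon alignments.
#' @param seed Default seed for generators called without one.
#' @return A list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(
    n_taxa = 64, depth = 300,
    clades = tibble::tibble(
      label = c("fish", "frogs", "birds", "mammals", "reptiles"),
      intercept = c(-1.35, -1.28, -1.32, -1.25, -1.30),
      slope = c(0.72, 0.70, 0.68, 0.71, 0.69)),
    bm_root = 2, bm_sigma2 = 0.01,
    sigma2_b = 0.001, r_scalar = 16,
    fast_set = c("tips", "clade", "subclades", "scattered"),
    fast_nclades = 3, fast_prob = 0.25, fast_clade = "frogs",
    ncodons = 300, branch_rate_sd = 0.5,
    rho = c(0.25, 1, 0.2, 0.3, 1.1, 0.25),
    pinuc = matrix(c(0.28, 0.24, 0.30, 0.18,
                     0.22, 0.28, 0.22, 0.28,
                     0.24, 0.26, 0.24, 0.26), 3, 4, byrow = TRUE,
                   dimnames = list(NULL, c("A", "C", "G", "T"))),
    alpha = 0.0025, omega = 0.2,
    coupling = 0, coupling_target = c("fast", "slow"), rate_coupling = 0,
    realized_threshold = 9, gamma = 0,
    outgroup = "Outgroup", outgroup_stem = 50, seed = 1) {
  coupling_target <- match.arg(coupling_target)
  fast_set <- match.arg(fast_set)
  stopifnot(n_taxa >= 3, depth > 0, sigma2_b > 0, r_scalar > 0,
            alpha > 0, omega > 0, coupling >= 0, branch_rate_sd >= 0,
            fast_prob >= 0, fast_prob <= 1)
  structure(list(n_taxa = n_taxa, depth = depth, clades = clades,
                 bm_root = bm_root, bm_sigma2 = bm_sigma2,
                 sigma2_b = sigma2_b, r_scalar = r_scalar,
                 fast_set = fast_set, fast_nclades = fast_nclades,
                 fast_prob = fast_prob,
                 fast_clade = fast_clade, ncodons = ncodons,
                 branch_rate_sd = branch_rate_sd, rho = rho,
                 pinuc = pinuc, alpha = alpha, omega = omega,
                 coupling = coupling, coupling_target = coupling_target,
                 rate_coupling = rate_coupling,
                 realized_threshold = realized_threshold,
                 gamma = gamma, outgroup = outgroup,
                 outgroup_stem = outgroup_stem, seed = seed),
            class = "simulation_scenario")
}

#' Simulate an ultrametric pure-birth tree
#'
#' @param n_taxa Number of tips (>= 3); labels `t1..tn`.
#' @param depth Tree depth (root-to-tip distance) after rescaling.
#' @param seed Integer seed.
#' @return A rooted ultrametric `phylo`.
#' @export
simulate_tree <- function(n_taxa, depth = 1, seed = 1) {
  if (n_taxa < 3) stop("need at least 3 taxa", call. = FALSE)
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  h <- max(node_depths(tr))
  tr$edge.length <- tr$edge.length * (depth / h)
  tr
}

# nnode x ntip logical matrix of tips below each node
.node_tip_matrix <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  below <- matrix(FALSE, nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in postorder_edges(tree))
    below[tree$edge[e, 1], ] <- below[tree$edge[e, 1], ] | below[tree$edge[e, 2], ]
  below
}

# monophyletic partition of tips into k groups, splitting the largest
# resolvable group at its root each time
assign_clades <- function(tree, k) {
  ntip <- ape::Ntip(tree)
  if (k == 1) return(setNames(rep(1L, ntip), tree$tip.label))
  below <- .node_tip_matrix(tree)
  root <- ntip + 1L
  children <- function(nd) tree$edge[tree$edge[, 1] == nd, 2]
  groups <- as.list(children(root))
  repeat {
    sizes <- vapply(groups, function(nd) sum(below[nd, ]), 0)
    if (length(groups) >= k) break
    splittable <- which(sizes > 1)
    if (!length(splittable)) break
    tgt <- splittable[which.max(sizes[splittable])]
    groups <- c(groups[-tgt], as.list(children(groups[[tgt]])))
  }
  lab <- integer(ntip)
  ord <- order(-vapply(groups, function(nd) sum(below[nd, ]), 0))
  for (g in seq_along(ord)) lab[below[groups[[ord[g]]], ]] <- g
  # merge singleton clades into the clade of the nearest tip: the clade-wise
  # regression needs at least two species per clade
  sizes <- tabulate(lab)
  if (any(sizes == 1) && length(unique(lab)) > 2) {
    dd <- ape::cophenetic.phylo(tree)
    for (g in which(sizes == 1)) {
      tip <- which(lab == g)
      other <- setdiff(seq_len(ntip), tip)
      lab[tip] <- lab[other[which.min(dd[tip, other])]]
    }
    lab <- match(lab, sort(unique(lab)))  # compact labels, keep size order
  }
  setNames(lab, tree$tip.label)
}

# per-edge Brownian increments and tip values for rate sigma2 * t * r
.bm_along_tree <- function(tree, sigma2, r_edge, root_value = 0) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  val <- numeric(nnode)
  val[ntip + 1L] <- root_value
  inc <- numeric(nrow(tree$edge))
  for (e in rev(postorder_edges(tree))) {  # preorder
    u <- tree$edge[e, 1]
    v <- tree$edge[e, 2]
    sdv <- sqrt(sigma2 * tree$edge.length[e] * r_edge[e])
    inc[e] <- rnorm(1, 0, sdv)
    val[v] <- val[u] + inc[e]
  }
  list(tips = val[seq_len(ntip)], increments = inc)
}

#' Simulate a trait table under the variable-rates regression model
#'
#' Body mass evolves by homogeneous Brownian motion; testes mass is the
#' clade-specific allometry plus a phylogenetic residual evolving by
#' Brownian motion whose variance on each branch is
#' `sigma2_b * t * r_true`, with `r_true = r_scalar` on the fast-branch set
#' (scattered or clade-wide, per the scenario) and 1 elsewhere.
#'
#' @param tree Ingroup tree (from [simulate_tree()]).
#' @param scenario A [simulation_scenario()].
#' @param seed Integer seed (defaults to the scenario's).
#' @return List with `traits` (trait tibble), `r_true` (a [branch_values()]
#'   tibble, kind `"r"`), `residual_increments` (per-edge, in
#'   `tree$edge` order), `fast_edges` (logical per edge).
#' @export
simulate_varrates_traits <- function(tree, scenario = simulation_scenario(),
                                     seed = scenario$seed) {
  set.seed(seed)
  k <- nrow(scenario$clades)
  grp <- assign_clades(tree, k)
  clade_lab <- scenario$clades$label[grp]
  M <- branch_tip_matrix(tree)
  if (scenario$fast_set == "scattered") {
    fast_edges <- runif(nrow(M)) < scenario$fast_prob
  } else if (scenario$fast_set == "tips") {
    terminal <- rowSums(M) == 1
    fast_edges <- terminal & (runif(nrow(M)) < scenario$fast_prob)
  } else if (scenario$fast_set == "subclades") {
    ntip <- ape::Ntip(tree)
    below <- .node_tip_matrix(tree)
    nsz <- rowSums(below)
    lo <- 3
    hi <- max(4, ceiling(ntip / 4))
    cands <- which(nsz >= lo & nsz <= hi)
    # prefer subtrees carrying the most branch time: deep bursts leave a
    # detectable variance signature, shallow ones do not
    subtree_time <- vapply(cands, function(nd) {
      sum(tree$edge.length[apply(M, 1, function(row)
        any(row) && all(row <= below[nd, ]))])
    }, 0)
    cands <- cands[order(-subtree_time + runif(length(cands), 0, 1e-3))]
    chosen <- integer(0)
    used <- rep(FALSE, ntip)
    for (nd in cands) {
      if (length(chosen) >= scenario$fast_nclades) break
      if (!any(below[nd, ] & used)) {
        chosen <- c(chosen, nd)
        used <- used | below[nd, ]
      }
    }
    fast_edges <- rep(FALSE, nrow(M))
    for (nd in chosen) {
      inset <- apply(M, 1, function(row) any(row) && all(row <= below[nd, ]))
      fast_edges <- fast_edges | inset
    }
  } else {
    fast_tips <- tree$tip.label[clade_lab == scenario$fast_clade]
    # edges strictly within the fast clade. The stem is left unscaled: a
    # x16 stem makes the whole clade's trait level drift as one enormous
    # excursion, which reads as a directional (level) effect rather than a
    # rate effect; the within-clade branches carry the detectable
    # overdispersion signature
    fast_edges <- apply(M, 1, function(row) {
      tl <- tree$tip.label[row]
      length(tl) > 0 && all(tl %in% fast_tips) && length(tl) < length(fast_tips)
    })
  }
  r_edge <- ifelse(fast_edges, scenario$r_scalar, 1)
  body <- .bm_along_tree(tree, scenario$bm_sigma2, rep(1, nrow(M)),
                         scenario$bm_root)
  resid <- .bm_along_tree(tree, scenario$sigma2_b, r_edge, 0)
  testes <- scenario$clades$intercept[grp] +
    scenario$clades$slope[grp] * body$tips + resid$tips
  traits <- tibble::tibble(species = tree$tip.label,
                           testes_mass_log10 = testes,
                           body_mass_log10 = body$tips,
                           clade = clade_lab)
  list(traits = traits,
       r_true = branch_values(tree, r_edge, kind = "r"),
       residual_increments = resid$increments,
       fast_edges = fast_edges)
}

#' Simulate a codon alignment with branch-specific rates
#'
#' The root codon is drawn from the F3x4 stationary distribution and evolved
#' along each branch with `P = expm(Q(dS_b, dN_b))`. Baseline rates are
#' `dS_b = alpha * t_b`, `dN_b = omega * alpha * t_b`; the scenario's rate
#' coupling multiplies `dN_b` by `(1 + c)` on the coupled branch set, and
#' its directional coupling by `exp(gamma * z_b)` with `z_b` the
#' standardized residual increment.
#'
#' @param tree Tree to evolve along (typically ingroup + outgroup, in Myr).
#' @param scenario A [simulation_scenario()].
#' @param seed Integer seed.
#' @param fast_edges Logical per edge of `tree`: the phenotypically fast
#'   set (defaults to none; pass the trait simulator's, lifted to this
#'   tree).
#' @param resid_z Standardized residual increments per edge (for
#'   directional coupling; defaults to zero).
#' @param resid_w Realized squared standardized increments relative to the
#'   background rate, per edge (for realized-rate coupling; defaults to 1).
#' @return List with `alignment` (a [codon_alignment()]), `truth` (tibble:
#'   branch, dS_true, dN_true), `dn_tree`, `ds_tree` (true branch-value
#'   trees).
#' @export
simulate_codon_alignment <- function(tree, scenario = simulation_scenario(),
                                     seed = scenario$seed,
                                     fast_edges = NULL, resid_z = NULL,
                                     resid_w = NULL) {
  set.seed(seed + 7L)
  E <- nrow(tree$edge)
  if (is.null(fast_edges)) fast_edges <- rep(FALSE, E)
  if (is.null(resid_z)) resid_z <- rep(0, E)
  if (is.null(resid_w)) resid_w <- rep(1, E)
  stopifnot(length(fast_edges) == E, length(resid_z) == E,
            length(resid_w) == E)
  dS <- scenario$alpha * tree$edge.length
  dN <- scenario$omega * dS
  if (scenario$branch_rate_sd > 0) {  # background branch-rate heterogeneity
    dS <- dS * exp(rnorm(E, 0, scenario$branch_rate_sd))
    dN <- dN * exp(rnorm(E, 0, scenario$branch_rate_sd))
  }
  # "slow" targets only branches off every fast species' root-to-tip path:
  # coupling an ancestor of fast tips would leak into their sums and dilute
  # the planted negative association
  M <- branch_tip_matrix(tree)
  fast_tips <- colSums(M[fast_edges, , drop = FALSE]) > 0
  off_fast_paths <- rowSums(M[, fast_tips, drop = FALSE]) == 0
  coupled <- if (scenario$coupling_target == "fast") fast_edges else
    off_fast_paths
  dN[coupled] <- dN[coupled] * (1 + scenario$coupling)
  if (scenario$rate_coupling != 0) {
    terminal <- rowSums(M) == 1
    fast_realized <- terminal & (resid_w > scenario$realized_threshold)
    cr <- scenario$rate_coupling
    if (cr > 0) {
      tgt <- fast_realized
    } else {
      # moderator: every branch off the realized-fast species' paths, so
      # the boost averages over many branches per species instead of
      # riding a single terminal's rate jitter
      fast_tip_cols <- colSums(M[fast_realized, , drop = FALSE]) > 0
      tgt <- rowSums(M[, fast_tip_cols, drop = FALSE]) == 0
    }
    dN[tgt] <- dN[tgt] * (1 + abs(cr))
  }
  dN <- dN * exp(scenario$gamma * resid_z)
  params <- mg94_params(rho = scenario$rho, pi = scenario$pinuc)
  gct <- genetic_code_tables()
  ord <- postorder_edges(tree)
  edges0 <- tree$edge[ord, , drop = FALSE] - 1L
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  Pc <- mg94_pmats_cpp(gct$changes, params$rho, params$pinuc, params$pi,
                       dS[ord], dN[ord])
  unif <- matrix(runif(nnode * scenario$ncodons), nnode, scenario$ncodons)
  st <- sim_codon_cpp(edges0, Pc, params$pi, nnode, ntip - 1L + 1L,
                      ntip, scenario$ncodons, unif)
  seqs <- apply(st + 1L, 1, function(row) paste(gct$codons[row], collapse = ""))
  aln <- codon_alignment(setNames(seqs, tree$tip.label))
  dn_tree <- tree
  dn_tree$edge.length <- dN
  ds_tree <- tree
  ds_tree$edge.length <- dS
  list(alignment = aln,
       truth = tibble::tibble(branch = branch_ids(tree),
                              dS_true = dS, dN_true = dN),
       dn_tree = dn_tree, ds_tree = ds_tree)
}

#' Archetype coupling settings for the benchmark bundle
#'
#' The six planted gene archetypes and the coupling settings that generate
#' them. `rate_coupling` ties the gene's non-synonymous rates to the
#' realized phenotypic branch speeds (positive: drivers; negative:
#' moderators); `gamma` ties them to the signed trait increments
#' (directional effects). Effect sizes were fixed once by pilot power runs
#' of the association pipeline at the benchmark scale.
#'
#' @return Tibble with columns `archetype`, `rate_coupling`, `gamma`,
#'   `label` (the planted classification).
#' @export
benchmark_archetypes <- function() {
  tibble::tibble(
    archetype = c("bidirectional_rapid_driver", "directional_rapid_driver",
                  "moderator", "directional_moderator",
                  "directional_nonrapid_driver", "null"),
    rate_coupling = c(30, 30, -30, -30, 0, 0),
    gamma = c(0, 1.5, 0, -1.5, 1.8, 0),
    label = c("bidirectional_rapid_driver", "directional_rapid_driver",
              "moderator", "directional_moderator",
              "directional_nonrapid_driver", "no_association")
  )
}

#' Generate the benchmark fixture bundle
#'
#' Writes the standard synthetic test input: one time tree (ingroup plus
#' outgroup), one trait table, one codon alignment per gene archetype, and a
#' truth file recording the planted rates and labels.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed; identical seeds give byte-identical bundles.
#' @param scenario A [simulation_scenario()].
#' @return Invisibly, a list with the manifest tibble and the truth list.
#' @export
generate_benchmark <- function(outdir, seed = 1,
                               scenario = simulation_scenario()) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok || file.access(outdir, 2) != 0)
    stop("cannot write to ", outdir, call. = FALSE)
  tree <- simulate_tree(scenario$n_taxa, scenario$depth, seed)
  sim_tr <- simulate_varrates_traits(tree, scenario, seed)
  full <- add_outgroup(tree, scenario$outgroup, scenario$outgroup_stem)
  # lift edge flags from the ingroup tree to the outgroup-bearing tree
  ids_full <- branch_ids(full)
  lift <- function(x, default) {
    m <- setNames(x, branch_ids(tree))
    out <- rep(default, length(ids_full))
    hit <- match(ids_full, names(m))
    out[!is.na(hit)] <- m[hit[!is.na(hit)]]
    out
  }
  fast_full <- as.logical(lift(sim_tr$fast_edges, FALSE))
  r_edge <- ifelse(sim_tr$fast_edges, scenario$r_scalar, 1)
  z <- sim_tr$residual_increments /
    sqrt(scenario$sigma2_b * tree$edge.length * r_edge)
  z[!is.finite(z)] <- 0
  z_full <- lift(z, 0)
  # realized branch speed relative to the background rate
  w <- sim_tr$residual_increments^2 / (scenario$sigma2_b * tree$edge.length)
  w[!is.finite(w)] <- 1
  w_full <- lift(w, 1)

  arch <- benchmark_archetypes()
  write_newick(full, file.path(outdir, "tree.nwk"))
  write_trait_table(sim_tr$traits, file.path(outdir, "traits.tsv"))
  truth <- list(seed = seed,
                fast_branches = branch_ids(tree)[sim_tr$fast_edges],
                r_scalar = scenario$r_scalar,
                archetypes = list())
  genes <- character(0)
  for (i in seq_len(nrow(arch))) {
    sc <- scenario
    sc$rate_coupling <- arch$rate_coupling[i]
    sc$gamma <- arch$gamma[i]
    g <- simulate_codon_alignment(full, sc, seed + i, fast_full, z_full,
                                  w_full)
    f <- file.path(outdir, paste0("gene_", arch$archetype[i], ".fasta"))
    write_codon_fasta(g$alignment, f)
    genes <- c(genes, f)
    truth$archetypes[[arch$archetype[i]]] <-
      list(label = arch$label[i], rate_coupling = arch$rate_coupling[i],
           gamma = arch$gamma[i])
  }
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- tibble::tibble(
    file = c("tree.nwk", "traits.tsv", basename(genes), "truth.json"),
    role = c("tree", "traits", paste0("gene:", arch$archetype), "truth"))
  invisible(list(dir = outdir, manifest = manifest, truth = truth,
                 tree = full, ingroup_tree = tree, traits = sim_tr$traits,
                 r_true = sim_tr$r_true))
}
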