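# Shared fixture builders. Everything is generated in code, seeded.

three_taxon_tree <- function() read_newick("((A:1,B:1):1,C:2);")

# brute-force multivariate normal log density (independent oracle)
dmvnorm_log <- function(x, mean, Sigma) {
  n <- length(x)
  d <- x - mean
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(Sigma, logarithm = TRUE)$modulus +
                       as.numeric(t(d) %*% solve(Sigma) %*% d)))
}

# an identity rate-scaled tree, for skip-path tests that never reach it
median_rate_tree_stub <- function(tree) tree

# root-to-tip distances (independent of the package's path-sum machinery)
node_depths_for_test <- function(tree) {
  ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
}

# a tiny trait table bound to a given tree, seeded
toy_traits <- function(tree, seed = 1, clades = 2) {
  set.seed(seed)
  n <- ape::Ntip(tree)
  cl <- rep_len(paste0("clade", seq_len(clades)), n)
  body <- rnorm(n, 2, 0.5)
  tibble::tibble(species = tree$tip.label,
                 testes_mass_log10 = -1 + 0.7 * body + rnorm(n, 0, 0.3),
                 body_mass_log10 = body,
                 clade = sort(cl))
}

# random MG94 parameter set
toy_params <- function(seed = 1) {
  set.seed(seed)
  pinuc <- matrix(stats::runif(12, 0.5, 1.5), 3, 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  pinuc <- pinuc / rowSums(pinuc)
  mg94_params(rho = c(0.3, 1, 0.2, 0.4, 1.1, 0.25), pi = pinuc)
}

# simulate a small codon alignment on a tree with given per-edge rates
toy_codon_aln <- function(tree, params, dS, dN, nsites = 30, seed = 1) {
  set.seed(seed)
  gct <- ratelink:::genetic_code_tables()
  ord <- ratelink:::postorder_edges(tree)
  edges0 <- tree$edge[ord, , drop = FALSE] - 1L
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  Pc <- ratelink:::mg94_pmats_cpp(gct$changes, params$rho, params$pinuc,
                                  params$pi, dS[ord], dN[ord])
  unif <- matrix(stats::runif(nnode * nsites), nnode, nsites)
  st <- ratelink:::sim_codon_cpp(edges0, Pc, params$pi, nnode, ntip,
                                 ntip, nsites, unif)
  seqs <- apply(st + 1L, 1, function(r) paste(gct$codons[r], collapse = ""))
  codon_alignment(stats::setNames(seqs, tree$tip.label))
}

# brute-force pruning likelihood by enumerating internal-node states
enum_loglik <- function(aln, tree, params, dS, dN) {
  gct <- ratelink:::genetic_code_tables()
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  states <- aln$states[match(tree$tip.label, aln$species), , drop = FALSE]
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    mg94_q_and_p(params, dS[e], dN[e])$P)
  internal <- (ntip + 1L):nnode
  grid <- do.call(expand.grid, rep(list(1:61), length(internal)))
  total <- 0
  for (s in seq_len(ncol(states))) {
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      asg <- integer(nnode)
      asg[seq_len(ntip)] <- states[, s]
      asg[internal] <- as.integer(grid[g, ])
      p <- params$pi[asg[ntip + 1L]]
      for (e in seq_len(nrow(tree$edge))) {
        u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
        if (is.na(asg[v])) next
        p <- p * Ps[[e]][asg[u], asg[v]]
      }
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}
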