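test_that("read_newick parses structure and applies defaults", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  root_children <- tr$edge[tr$edge[, 1] == ape::Ntip(tr) + 1, 2]
  expect_length(root_children, 2)

  tr0 <- read_newick("(A,B);")
  expect_equal(tr0$edge.length, c(0, 0))

  expect_error(read_newick("((A:1,B:1):1,C:2;"), "paren")
  expect_error(read_newick("((A:1,A:1):1,C:2);"), "duplicate")
})

test_that("newick writing round-trips random trees", {
  for (seed in 1:20) {
    tr <- simulate_tree(sample(5:50, 1), depth = 1, seed = seed)
    txt <- write_newick(tr)
    tr2 <- read_newick(txt)
    expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
    # same topology and lengths under the stable branch-id keying
    bv1 <- setNames(tr$edge.length, branch_ids(tr))
    bv2 <- setNames(tr2$edge.length, branch_ids(tr2))
    expect_equal(bv2[names(bv1)], bv1, tolerance = 1e-8)
  }
})

test_that("match_and_prune handles exact, genus and ambiguous matches", {
  tr <- read_newick("((Mus_musculus:1,Rattus_norvegicus:1):1,Canis_lupus:2);")
  r1 <- match_and_prune(tr, c("Mus musculus", "Canis_lupus"))
  expect_setequal(r1$tree$tip.label, c("Mus_musculus", "Canis_lupus"))
  expect_equal(sort(r1$report$match), c("exact", "exact"))

  r2 <- match_and_prune(tr, c("Mus_spretus", "Canis_lupus"),
                        genus_fallback = TRUE)
  expect_equal(r2$report$match[r2$report$query == "Mus_spretus"], "genus")
  expect_true("Mus_spretus" %in% r2$tree$tip.label)  # relabelled to query

  tr2 <- read_newick("((Mus_musculus:1,Mus_caroli:1):1,Canis_lupus:2);")
  r3 <- match_and_prune(tr2, c("Mus_spretus", "Canis_lupus"))
  expect_equal(r3$report$match[r3$report$query == "Mus_spretus"], "unmatched")

  expect_error(match_and_prune(tr, c("Homo_sapiens")), "matched")
})

test_that("scale_branches multiplies lengths and preserves topology", {
  tr <- three_taxon_tree()
  ident <- scale_branches(tr, rep(1, nrow(tr$edge)))
  expect_equal(ident$edge.length, tr$edge.length)

  set.seed(3)
  tr2 <- simulate_tree(20, depth = 10, seed = 3)
  r <- runif(nrow(tr2$edge), 0.1, 5)
  sc <- scale_branches(tr2, branch_values(tr2, r, "r"))
  expect_equal(sum(sc$edge.length), sum(tr2$edge.length * r))
  expect_identical(sc$edge, tr2$edge)

  expect_error(scale_branches(tr, rep(1, 2)), "per branch")
})

test_that("root_to_tip sums follow paths and match covariance diagonal", {
  tr <- three_taxon_tree()
  rts <- root_to_tip_sum(tr)
  expect_equal(setNames(rts$total, rts$species),
               c(A = 2, B = 2, C = 2))

  vals <- setNames(c(3, 1, 1, 5),
                   c(branch_ids(tr)))
  # assign named values: A-branch 3, AB-stem 1, B-branch 1, C-branch 5
  ids <- branch_ids(tr)
  v <- numeric(4)
  v[ids == "A"] <- 3; v[ids == "A|B"] <- 1; v[ids == "B"] <- 1; v[ids == "C"] <- 5
  rts2 <- root_to_tip_sum(tr, branch_values(tr, v, "dN"))
  expect_equal(setNames(rts2$total, rts2$species), c(A = 4, B = 2, C = 5))

  for (seed in 1:5) {
    tr3 <- simulate_tree(15, depth = 2, seed = seed)
    V <- phylo_covariance(tr3)
    rts3 <- root_to_tip_sum(tr3)
    expect_equal(rts3$total, unname(diag(V)[rts3$species]), tolerance = 1e-10)
  }

  expect_error(root_to_tip_sum(ape::unroot(simulate_tree(5, 1, 1))),
               "unrooted")
})

test_that("phylo_covariance matches the hand example, star trees and ape", {
  V <- phylo_covariance(three_taxon_tree())
  expect_equal(unname(V[c("A", "B", "C"), c("A", "B", "C")]),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3))

  star <- read_newick("(A:1,B:2,C:3,D:4);")
  expect_equal(unname(phylo_covariance(star)), diag(c(1, 2, 3, 4)))

  tr <- simulate_tree(20, depth = 5, seed = 11)
  V2 <- phylo_covariance(tr)
  expect_gte(min(eigen(V2, symmetric = TRUE, only.values = TRUE)$values),
             -1e-9)
  # independent route: ape's vcv
  expect_equal(V2[tr$tip.label, tr$tip.label],
               ape::vcv(tr)[tr$tip.label, tr$tip.label], tolerance = 1e-10)
})

test_that("scaling all branches by c scales the covariance exactly", {
  tr <- simulate_tree(12, depth = 3, seed = 5)
  sc <- scale_branches(tr, rep(2.5, nrow(tr$edge)))
  expect_equal(phylo_covariance(sc), 2.5 * phylo_covariance(tr),
               tolerance = 1e-12)
})

test_that("trait tables log-transform exactly once and round-trip", {
  tmp <- tempfile(fileext = ".tsv")
  df <- data.frame(species = c("A sp", "B_sp"), testes_mass_g = c(1, 100),
                   body_mass_g = c(10, 1000), clade = "m")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  tt <- read_trait_table(tmp)
  expect_equal(tt$testes_mass_log10, c(0, 2))
  expect_equal(tt$species, c("A_sp", "B_sp"))
  tmp2 <- tempfile(fileext = ".tsv")
  write_trait_table(tt, tmp2)
  expect_equal(read_trait_table(tmp2), tt)
  unlink(c(tmp, tmp2))
})
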