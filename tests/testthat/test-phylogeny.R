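# Polarization, haplotype collapsing, four-gamete test, perfect
# phylogeny vs. exhaustive parsimony, liftover.

test_that("polarization recodes against the outgroup and drops blind sites", {
  S <- rbind(A = c(0L, 1L, 0L), B = c(1L, 1L, 1L), OUT = c(1L, 0L, NA))
  colnames(S) <- c("v1", "v2", "v3")
  m <- haplo_matrix(S, "OUT")
  expect_warning(p <- polarize(m), "dropped")
  ps <- unclass_states(p)
  expect_equal(ncol(ps), 2L)
  expect_equal(ps["OUT", ], c(v1 = 0L, v2 = 0L))
  expect_equal(ps["A", "v1"], 1L)   # labels swapped where outgroup carried alt
  expect_equal(ps["B", "v1"], 0L)
  # secondary outgroup rescues the blind site
  S2 <- rbind(S, OUT2 = c(1L, 0L, 0L))
  m2 <- haplo_matrix(S2, "OUT")
  p2 <- polarize(m2, secondary_outgroup_id = "OUT2")
  expect_equal(ncol(unclass_states(p2)), 3L)
  expect_error(polarize(haplo_matrix(S, "OUT"), "missing_row"), "outgroup")
})

test_that("polarization recovers simulator truth exactly", {
  sim <- simulate_infinite_sites(n_leaves = 8, expected_per_branch = 4,
                                 outgroup_mutations = 3,
                                 scramble_polarity = 0.5, seed = 5)
  expect_gt(length(sim$flipped_sites), 0)
  pol <- polarize(sim$matrix)
  expect_identical(unclass_states(pol), sim$truth)
})

test_that("haplotype collapsing partitions by compatible identity", {
  S <- rbind(A = c(1L, 0L), B = c(1L, 0L), C = c(1L, 0L))
  colnames(S) <- c("v1", "v2")
  one <- collapse_haplotypes(hm(S))
  expect_equal(lengths(one$haplotypes)[["H1"]], 3L)
  S2 <- rbind(A = c(1L, 0L), B = c(1L, 1L))
  colnames(S2) <- c("v1", "v2")
  two <- collapse_haplotypes(hm(S2))
  expect_equal(length(two$haplotypes), 3L)   # A, B, outgroup
  # missing entries are wildcards: joins the first compatible group
  S3 <- rbind(A = c(1L, 0L), B = c(1L, NA))
  colnames(S3) <- c("v1", "v2")
  expect_equal(length(collapse_haplotypes(hm(S3))$haplotypes), 2L)
})

test_that("planted haplotypes are recovered from replicated samples", {
  sim <- simulate_infinite_sites(n_leaves = 7, expected_per_branch = 3,
                                 samples_per_leaf = 3, seed = 9)
  coll <- collapse_haplotypes(sim$matrix)
  # 7 planted ingroup haplotypes (+1 all-ancestral outgroup, unless some
  # leaf drew zero mutations on its pendant path and merged with it)
  counts <- table(sub("_.*", "", unlist(coll$haplotypes)))
  expect_equal(length(coll$haplotypes), 8L)
  expect_true(all(counts[paste0("S", 1:7)] == 3L))
})

test_that("four-gamete test flags exactly the textbook violations", {
  bad <- rbind(A = c(0L, 0L), B = c(0L, 1L), C = c(1L, 0L), D = c(1L, 1L))
  colnames(bad) <- c("s1", "s2")
  res <- four_gamete_check(hm(bad))
  expect_false(res$compatible)
  expect_equal(res$incompatible_pairs,
               data.frame(site1 = "s1", site2 = "s2",
                          stringsAsFactors = FALSE))
  nested <- rbind(A = c(1L, 1L), B = c(1L, 0L), C = c(0L, 0L))
  colnames(nested) <- c("big", "small")
  expect_true(four_gamete_check(hm(nested))$compatible)
  for (s in 1:5)
    expect_true(four_gamete_check(
      simulate_infinite_sites(n_leaves = 8, seed = s)$matrix)$compatible)
})

test_that("perfect phylogeny reproduces the worked 4-taxon example", {
  S <- rbind(A = c(1L, 1L, 0L), B = c(1L, 0L, 0L),
             C = c(0L, 0L, 1L), D = c(0L, 0L, 0L))
  colnames(S) <- c("s1", "s2", "s3")
  tr <- build_perfect_phylogeny(hm(S))
  expect_equal(tree_length(tr), 3L)
  counts <- branch_mutation_counts(tr)
  hap_of <- function(sample) {
    names(tr$haplotypes)[vapply(tr$haplotypes, function(m) sample %in% m,
                                logical(1))]
  }
  # private mutations: s2 on A, s3 on C; s1 on the (A,B) stem
  expect_equal(unname(counts[hap_of("A")]), 1L)
  expect_equal(unname(counts[hap_of("C")]), 1L)
  stem <- tr$edges$parent[tr$edges$child == hap_of("A")]
  expect_equal(unname(counts[stem]), 1L)
  expect_setequal(tr$branch_sites[[stem]], "s1")
  # the (A,B) cherry exists: A and B share a parent that is not the root
  expect_equal(tr$edges$parent[tr$edges$child == hap_of("B")], stem)
  expect_false(stem == "root")
  expect_equal(sum(counts), 3L)
})

test_that("single lineage and incompatible inputs behave as specified", {
  S <- matrix(rep(1L, 5), 1, dimnames = list("A", paste0("v", 1:5)))
  tr <- build_perfect_phylogeny(hm(S))
  expect_equal(tree_length(tr), 5L)
  expect_equal(max(branch_mutation_counts(tr)), 5L)
  bad <- rbind(A = c(0L, 0L), B = c(0L, 1L), C = c(1L, 0L), D = c(1L, 1L))
  colnames(bad) <- c("s1", "s2")
  expect_error(build_perfect_phylogeny(hm(bad)), "s1/s2")
  expect_error(build_perfect_phylogeny(
    haplo_matrix(rbind(A = 1L, OUT = 0L), "OUT")), "polarized")
})

test_that("reconstruction matches the simulating topology", {
  for (s in c(2, 8, 21)) {
    sim <- simulate_infinite_sites(n_leaves = 10, expected_per_branch = 3,
                                   seed = s)
    tr <- build_perfect_phylogeny(sim$matrix)
    expect_equal(tree_length(tr), ncol(sim$matrix))
    # clades with >= 1 supporting mutation must appear in the true tree
    # (zero-mutation branches collapse to polytomies)
    true_phylo <- sim$tree
    tips_below <- function(tree, node) {
      nt <- length(tree$tip.label)
      if (node <= nt) return(tree$tip.label[node])
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      sort(unlist(lapply(kids, tips_below, tree = tree)))
    }
    true_clades <- vapply(
      true_phylo$edge[true_phylo$edge.length > 0, 2],
      function(nd) paste(tips_below(true_phylo, nd), collapse = "|"),
      character(1))
    members <- function(node) {
      kids <- tr$edges$child[tr$edges$parent == node]
      if (!length(kids)) return(tr$haplotypes[[node]])
      unlist(lapply(kids, members))
    }
    built_clades <- vapply(
      tr$edges$child[tr$edges$mutations > 0],
      function(nd) paste(sort(members(nd)), collapse = "|"), character(1))
    built_clades <- built_clades[!grepl("OUT", built_clades)]
    expect_true(all(sort(built_clades) %in% sort(true_clades)))
    expect_setequal(true_clades[!grepl("OUT", true_clades)], built_clades)
  }
})

test_that("tree length equals exhaustive parsimony on compatible matrices", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    sim <- simulate_infinite_sites(n_leaves = n, expected_per_branch = 2,
                                   outgroup_mutations = 1,
                                   seed = sample.int(1e6, 1))
    if (ncol(sim$matrix) == 0) next
    expect_equal(tree_length(build_perfect_phylogeny(sim$matrix)),
                 mp_length_exhaustive(sim$matrix))
  }
})

test_that("exhaustive parsimony oracle behaves on edge cases", {
  two <- haplo_matrix(rbind(A = c(1L, 1L, 1L), OUT = c(0L, 0L, 0L)), "OUT",
                      polarized = TRUE)
  expect_equal(mp_length_exhaustive(two), 3)
  # one four-gamete violation forces exactly one extra step
  bad <- rbind(A = c(0L, 0L), B = c(0L, 1L), C = c(1L, 0L), D = c(1L, 1L))
  colnames(bad) <- c("s1", "s2")
  expect_equal(mp_length_exhaustive(hm(bad)), 3)
  big <- matrix(0L, 9, 2, dimnames = list(paste0("S", 1:9), NULL))
  expect_error(mp_length_exhaustive(haplo_matrix(big, "S1")), "8 taxa")
})

test_that("dropping a sample never increases tree length", {
  for (s in 1:5) {
    sim <- simulate_infinite_sites(n_leaves = 8, expected_per_branch = 3,
                                   seed = s)
    S <- unclass_states(sim$matrix)
    full <- tree_length(build_perfect_phylogeny(sim$matrix))
    drop <- setdiff(rownames(S), "OUT")[1]
    S2 <- S[setdiff(rownames(S), drop), , drop = FALSE]
    S2 <- S2[, colSums(S2 == 1L, na.rm = TRUE) > 0, drop = FALSE]
    if (ncol(S2) == 0) next
    sub <- tree_length(build_perfect_phylogeny(
      haplo_matrix(S2, "OUT", polarized = TRUE)))
    expect_lte(sub, full)
  }
})

test_that("collapse -> build -> leaf expansion round-trips the partition", {
  sim <- simulate_infinite_sites(n_leaves = 6, expected_per_branch = 4,
                                 samples_per_leaf = 2, seed = 4)
  coll <- collapse_haplotypes(sim$matrix)
  tr <- build_perfect_phylogeny(sim$matrix)
  expect_identical(tr$haplotypes, coll$haplotypes)
  expect_setequal(unlist(tr$haplotypes), rownames(sim$matrix))
})

test_that("as_phylo yields a valid ape tree with mutation branch lengths", {
  sim <- simulate_infinite_sites(n_leaves = 6, expected_per_branch = 3,
                                 seed = 6)
  tr <- build_perfect_phylogeny(sim$matrix)
  phy <- as_phylo(tr)
  expect_s3_class(phy, "phylo")
  # the outgroup haplotype hangs directly off the root (basal polytomies
  # are legitimate, so ape::is.rooted() is not the right predicate)
  og_tip <- which(phy$tip.label == tr$outgroup)
  root_node <- length(phy$tip.label) + 1L
  expect_true(any(phy$edge[, 1] == root_node & phy$edge[, 2] == og_tip))
  expect_equal(sum(phy$edge.length), tree_length(tr))
  expect_setequal(phy$tip.label, tr$leaves)
})

test_that("bootstrap support is high for mutation-rich clades", {
  sim <- simulate_infinite_sites(n_leaves = 6, expected_per_branch = 8,
                                 seed = 12)
  bs <- bootstrap_support(sim$matrix, n_reps = 40, seed = 3)
  expect_true(all(bs >= 0 & bs <= 1))
  expect_gt(mean(bs), 0.8)
})

test_that("STR allele arithmetic adds repeat units to the amplicon", {
  expect_equal(str_allele_length(204, 4, 1), 208)
  expect_equal(str_allele_length(204, 4, -1), 200)
})

test_that("flank liftover finds planted, absent and duplicated sites", {
  set.seed(77)
  contig <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  target <- Biostrings::DNAStringSet(c(chr1 = contig))
  pos <- 4001L                       # 1-based position of the variant base
  left <- substr(contig, pos - 50, pos - 1)
  right <- substr(contig, pos + 1, pos + 50)
  res <- liftover_by_flank(left, right, 1L, target)
  expect_equal(res$status, "unique")
  expect_equal(res$pos, pos)
  expect_equal(res$strand, "+")
  # reverse strand: search with the flanks of the reverse complement
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  res_rc <- liftover_by_flank(rc(right), rc(left), 1L, target)
  expect_equal(res_rc$status, "unique")
  expect_equal(res_rc$strand, "-")
  expect_equal(res_rc$pos, pos)
  expect_equal(liftover_by_flank("ACGTACGTACGT", "TTTTGGGGCCCC", 1L,
                                 target)$status, "absent")
  dup <- Biostrings::DNAStringSet(c(chr1 = paste0(contig, contig)))
  expect_equal(liftover_by_flank(left, right, 1L, dup)$status, "ambiguous")
  expect_error(liftover_by_flank("", right, 1L, target), "non-empty")
})

test_that("liftover of simulated variants onto their own assembly is exact", {
  set.seed(123)
  contig <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  target <- Biostrings::DNAStringSet(c(ctg = contig))
  for (pos in c(301L, 2500L, 4600L)) {
    res <- liftover_by_flank(substr(contig, pos - 50, pos - 1),
                             substr(contig, pos + 1, pos + 50), 1L, target)
    expect_equal(res$status, "unique")
    expect_equal(res$pos, pos)
  }
})
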