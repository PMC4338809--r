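test_that("affinity TSV round-trips and rejects malformed input", {
  m <- toy_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_affinity(m, path)
  m2 <- read_affinity(path)
  expect_identical(unclass(m2), unclass(m))
  expect_identical(rowSums(m2), c(spA = 3, spB = 2, spC = 0, spD = 3))

  # non-binary cell named by row/column
  bad <- readLines(path)
  bad[2] <- sub("\t1", "\t2", bad[2])
  writeLines(bad, path)
  expect_error(read_affinity(path), class = "microstab_format_error")
  expect_error(read_affinity(path), "spA")

  # duplicate species id
  write_affinity(m, path)
  dup <- readLines(path)
  dup[3] <- sub("spB", "spA", dup[3])
  writeLines(dup, path)
  expect_error(read_affinity(path), class = "microstab_format_error")

  expect_error(affinity_matrix(matrix(c(0, 2), 1)),
               class = "microstab_format_error")
})

test_that("niche breadth matches a loop-and-count oracle", {
  m <- toy_matrix()
  expect_identical(niche_breadth(m, "spC"), 0L)  # empty niche
  full <- affinity_matrix(matrix(1L, 1, 95, dimnames = list("g", NULL)))
  expect_identical(niche_breadth(full, "g"), 95L)
  expect_error(niche_breadth(m, "nope"), class = "microstab_lookup_error")

  set.seed(7)
  for (i in 1:20) {
    r <- random_affinity(1, 40)
    hand <- sum(vapply(seq_len(40), function(j) r[1, j] == 1L, logical(1)))
    expect_identical(unname(niche_breadth(r, rownames(r))), hand)
  }
})

test_that("CMD is the set union and respects its bounds", {
  m <- toy_matrix()
  # singleton: union of one set = breadth
  expect_identical(community_metabolic_diversity(m, "spA"), 3L)
  # disjoint profiles add
  d <- affinity_matrix(rbind(a = c(rep(1, 10), rep(0, 10)),
                             b = c(rep(0, 13), rep(1, 7))))
  expect_identical(community_metabolic_diversity(d, c("a", "b")), 17L)
  expect_error(community_metabolic_diversity(m, character(0)),
               class = "microstab_domain_error")

  set.seed(11)
  for (i in 1:50) {
    r <- random_affinity(8, 60, p = runif(1, 0.1, 0.6))
    members <- sample(rownames(r), 5)
    expect_identical(community_metabolic_diversity(r, members),
                     oracle_cmd(r, members))
    # bounds and monotonicity under member addition
    cmd <- community_metabolic_diversity(r, members)
    br <- rowSums(r[members, , drop = FALSE])
    expect_gte(cmd, max(br))
    expect_lte(cmd, min(sum(br), ncol(r)))
    extra <- sample(setdiff(rownames(r), members), 1)
    expect_gte(community_metabolic_diversity(r, c(members, extra)), cmd)
  }
})

test_that("pairwise overlap is the Jaccard index", {
  m <- toy_matrix()
  same <- affinity_matrix(rbind(a = c(1, 0, 1), b = c(1, 0, 1)))
  expect_equal(pairwise_overlap(same, "a", "b"), 1)
  disj <- affinity_matrix(rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1)))
  expect_equal(pairwise_overlap(disj, "a", "b"), 0)
  tri <- affinity_matrix(rbind(a = c(1, 1, 0, 0), b = c(0, 1, 1, 0)))
  expect_equal(pairwise_overlap(tri, "a", "b"), 1 / 3)
  zz <- affinity_matrix(rbind(a = c(0, 0), b = c(0, 0)))
  expect_error(pairwise_overlap(zz, "a", "b"),
               class = "microstab_undefined_overlap_error")

  set.seed(3)
  for (i in 1:20) {
    r <- random_affinity(2, 30, p = 0.5)
    expect_equal(pairwise_overlap(r, rownames(r)[1], rownames(r)[2]),
                 oracle_jaccard(r, rownames(r)[1], rownames(r)[2]))
  }
})

test_that("redundancy is 1 - CMD/sum(breadths), zero iff disjoint", {
  k <- 4; b <- 6
  ident <- affinity_matrix(matrix(rep(c(rep(1, b), rep(0, 14)), k),
                                  nrow = k, byrow = TRUE))
  expect_equal(community_redundancy(ident, rownames(ident)), (k - 1) / k)
  disj <- affinity_matrix(diag(1L, 5))
  expect_equal(community_redundancy(disj, rownames(disj)), 0)
  zz <- affinity_matrix(rbind(a = c(0, 0), b = c(0, 0)))
  expect_error(community_redundancy(zz, c("a", "b")),
               class = "microstab_domain_error")

  set.seed(5)
  for (i in 1:30) {
    r <- random_affinity(6, 40, p = runif(1, 0.2, 0.6))
    members <- sample(rownames(r), 4)
    if (sum(r[members, ]) == 0) next
    expect_equal(community_redundancy(r, members),
                 oracle_redundancy(r, members))
    # redundancy 0 <=> all pairwise overlaps (defined ones) are 0
    nm <- niche_metrics(r, members)
    nz <- members[rowSums(r[members, , drop = FALSE]) > 0]
    ovl <- if (length(nz) > 1) {
      combn(nz, 2, function(p) pairwise_overlap(r, p[1], p[2]))
    } else 0
    expect_equal(nm$redundancy == 0, all(ovl == 0))
  }
})

test_that("build_design reproduces the 17-consortium nested layout", {
  pool <- sprintf("sp%02d", 1:12)
  d <- build_design(pool)
  expect_length(d$consortia, 17)
  expect_identical(d$replicates, 3L)
  byname <- function(lvl, comp) {
    Filter(function(co) co$level == lvl && co$composition_label == comp,
           d$consortia)[[1]]
  }
  expect_identical(byname(2, "B")$members, pool[6:7])
  expect_identical(byname(4, "B")$members, pool[5:8])
  # the published table prints only six strains for 7C; reproduced as printed
  expect_identical(byname(7, "C")$members, pool[7:12])
  expect_identical(byname(7, "C")$richness, 6L)
  expect_identical(byname(11, "single")$members, pool[1:11])
  # 17 consortia x 3 replicates = 51 experimental units
  expect_identical(length(d$consortia) * d$replicates, 51L)
  expect_error(build_design(pool[1:11]), class = "microstab_design_error")

  # nested chains: A, B, C are each increasing by inclusion
  for (comp in c("A", "B", "C")) {
    chain <- Filter(function(co) co$composition_label == comp, d$consortia)
    for (i in seq_len(length(chain) - 1)) {
      expect_true(all(chain[[i]]$members %in% chain[[i + 1]]$members))
    }
  }

  # design JSON round-trip
  path <- withr::local_tempfile(fileext = ".json")
  write_design(d, path)
  d2 <- read_design(path)
  expect_identical(lapply(d2$consortia, `[[`, "members"),
                   lapply(d$consortia, `[[`, "members"))
})

test_that("cmd_richness_curve handles degenerate and disjoint matrices", {
  pool <- sprintf("sp%02d", 1:12)
  # all species identical: flat curve at the common breadth
  prof <- c(rep(1L, 9), rep(0L, 11))
  ident <- affinity_matrix(matrix(rep(prof, 12), nrow = 12, byrow = TRUE),
                           species_ids = pool)
  cc <- cmd_richness_curve(ident, build_design(pool))
  expect_true(all(cc$cmd == 9))
  # pairwise disjoint species of breadth 5: CMD = 5 * member count
  disj <- affinity_matrix(
    t(sapply(0:11, function(i) as.integer(seq_len(95) %in% (i * 5 + 1:5)))),
    species_ids = pool)
  cc2 <- cmd_richness_curve(disj, build_design(pool))
  expect_identical(cc2$cmd, 5L * cc2$richness)
})

test_that("expected CMD curve at generator defaults saturates (concave mean)", {
  cmds <- NULL
  for (s in 1:15) {
    cfg <- generator_config(seed = 400 + s)
    m <- generate_affinity_matrix(cfg)
    cc <- cmd_richness_curve(m, build_design(rownames(m)))
    a <- cc[cc$composition %in% c("A", "single"), ]
    cmds <- rbind(cmds, a$cmd[order(a$richness)])
  }
  rich <- sort(c(2, 3, 4, 5, 7, 11, 12))
  mean_curve <- colMeans(cmds)
  slopes <- diff(mean_curve) / diff(rich)
  expect_true(all(diff(slopes) <= 0))
  expect_true(all(diff(mean_curve) >= 0))
})
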