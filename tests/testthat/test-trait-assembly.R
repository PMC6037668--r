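# Fixture: 2 samples x 4 taxa, one taxon lacking a family assignment.
tiny_counts <- function() {
  counts <- matrix(c(5, 7, 3, 2,
                     1, 0, 4, 8), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), paste0("otu", 1:4)))
  lineage <- c("k1;p1;c1;o1;f1;g1",
               "k1;p1;c1;o1;f2;g2",
               "k1;p1;c2;o2;f3;g3",
               "k1;p1;c2;o2;;")  # unassigned family/genus
  taxon_counts(counts, lineage)
}

test_that("taxonomic collapsing sums counts and drops unassigned taxa", {
  tc <- tiny_counts()
  cls <- collapse_to_level(tc, "class")
  # two families in one class: 5 + 7 = 12 for sample s1
  expect_equal(unname(cls$counts["s1", "k1;p1;c1"]), 12)
  expect_equal(ncol(cls$counts), 2L)
  fam <- collapse_to_level(tc, "family")
  # otu4 has no family assignment and must be excluded
  expect_equal(ncol(fam$counts), 3L)
  expect_true(all(rowSums(fam$counts) <= rowSums(tc$counts)))
  expect_true(all(rowSums(cls$counts) == rowSums(tc$counts)))
  expect_error(collapse_to_level(tc, "phylum"), "unknown rank")
})

test_that("log relative abundance follows the pseudocount formula", {
  one <- taxon_counts(matrix(10, 1, 1, dimnames = list("s", "t")),
                      "k;p;c;o;f;g")
  expect_equal(unname(log_relative_abundance(one, pseudocount = 0)[1, 1]), 0)
  two <- taxon_counts(matrix(c(50, 50), 1, 2,
                             dimnames = list("s", c("a", "b"))),
                      c("k;p;c;o;f1;g1", "k;p;c;o;f2;g2"))
  la <- log_relative_abundance(two, pseudocount = 0)
  expect_equal(unname(la[1, ]), rep(log(0.5), 2))
  # zero count with pseudocount 0.5, depth 100, 2 taxa -> log(0.5 / 101)
  zc <- taxon_counts(matrix(c(0, 100), 1, 2,
                            dimnames = list("s", c("a", "b"))),
                     c("k;p;c;o;f1;g1", "k;p;c;o;f2;g2"))
  expect_equal(unname(log_relative_abundance(zc, 0.5)[1, 1]), log(0.5 / 101))
  # adjusted relative abundances sum to one before the log
  m <- matrix(c(3, 0, 9, 1, 1, 1), 2, 3)
  ra <- exp(log_relative_abundance(m, 0.5))
  expect_equal(rowSums(ra), rep(1, 2), tolerance = 1e-12)
  expect_error(log_relative_abundance(matrix(0, 1, 2)), "zero-depth")
})

test_that("Shannon index matches closed forms and vegan, richness counts", {
  expect_equal(shannon_index(c(5)), 0)
  expect_equal(shannon_index(c(1, 1, 1, 1)), 2)
  expect_equal(shannon_index(c(2, 1, 1)), 1.5)
  expect_error(shannon_index(c(0, 0)), "all-zero")
  set.seed(8)
  for (i in 1:10) {
    x <- rpois(12, 5) + ifelse(runif(12) < 0.3, 0, 1)
    if (sum(x) == 0) next
    expect_equal(shannon_index(x, base = exp(1)),
                 vegan::diversity(x, index = "shannon"),
                 tolerance = 1e-12)
    # uniform distribution maximizes Shannon at fixed richness
    k <- sum(x > 0)
    expect_lte(shannon_index(x), log2(k) + 1e-12)
  }
  expect_equal(richness(c(0, 0, 0)), 0)
  expect_equal(richness(c(1, 0, 3)), 2)
  expect_equal(richness(c(1, 0, 3) + c(1, 0, 0)), 2)
})

test_that("PCoA recovers collinear points and returns orthogonal axes", {
  pos <- c(0, 1, 3, 7)
  D <- as.matrix(dist(pos))
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  ax <- pcoa_axes(D, k = 2)
  expect_equal(abs(cor(ax[, 1], pos)), 1, tolerance = 1e-8)
  # Euclidean input: distances reconstructed from the axes
  expect_equal(as.matrix(dist(ax[, 1])), D, ignore_attr = TRUE,
               tolerance = 1e-8)
  # orthogonality and eigenvalue ordering
  g <- crossprod(ax)
  expect_lt(abs(g[1, 2]), 1e-8)
  ev <- attr(ax, "eigenvalues")
  expect_true(all(diff(ev) <= 1e-8))
  # degenerate all-zero matrix
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(az <- pcoa_axes(z, k = 2), "zero-filling")
  expect_true(all(az == 0))
  bad <- D; bad[1, 2] <- 99
  expect_error(pcoa_axes(bad, 2), "symmetric")
})

test_that("assembled trait set has the expected composition", {
  set.seed(15)
  n_s <- 10
  # 10 classes x 4 families each = 40 family traits, 10 class traits
  lin <- unlist(lapply(1:10, function(ci) {
    sprintf("k;p;c%02d;o%02d;f%02d_%d;g", ci, ci, ci, 1:4)
  }))
  counts <- matrix(rpois(n_s * 40, 20) + 1, n_s, 40,
                   dimnames = list(sprintf("s%02d", 1:n_s), NULL))
  colnames(counts) <- sprintf("otu%02d", 1:40)
  tc <- taxon_counts(counts, lin)
  alpha <- matrix(rnorm(n_s * 3), n_s, 3,
                  dimnames = list(rownames(counts),
                                  c("shannon", "pd", "richness")))
  mkdist <- function(seed) {
    set.seed(seed)
    d <- as.matrix(dist(matrix(rnorm(n_s * 3), n_s)))
    dimnames(d) <- list(rownames(counts), rownames(counts))
    d
  }
  dms <- list(wuf = mkdist(1), uuf = mkdist(2))
  tm <- assemble_initial_traits(tc, alpha, dms)
  info <- attr(tm, "trait_info")
  expect_equal(ncol(tm), 40 + 10 + 3 + 12)
  kind_counts <- table(info$kind)
  expect_equal(as.integer(kind_counts[c("taxon_class", "taxon_family",
                                        "alpha", "beta_axis")]),
               c(10L, 40L, 3L, 12L))
  # two alpha columns accepted with a warning
  expect_warning(assemble_initial_traits(tc, alpha[, 1:2], dms),
                 "expected 3")
  # sample-index mismatch rejected
  bad_alpha <- alpha; rownames(bad_alpha)[1] <- "nope"
  expect_error(assemble_initial_traits(tc, bad_alpha, dms), "mismatch")
})
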