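test_that("random gene-set sampling is uniform, exhaustive and reproducible", {
  pool <- c("A", "B", "C", "D", "E")
  expect_setequal(sample_random_geneset(pool, 5)$genes, pool)
  expect_error(sample_random_geneset(pool, 6), "exceeds pool")

  set.seed(31)
  a <- sample_random_geneset(pool, 3)$genes
  set.seed(31)
  b <- sample_random_geneset(pool, 3)$genes
  expect_identical(a, b)

  # inclusion frequency of each gene over 10000 draws of size 2 is
  # Binomial(10000, 2/5): stay within 3 standard errors of 0.4
  set.seed(32)
  draws <- replicate(10000, sample_random_geneset(pool, 2)$genes)
  freq <- table(factor(draws, levels = pool)) / 10000
  se <- sqrt(0.4 * 0.6 / 10000)
  expect_true(all(abs(freq - 0.4) < 3 * se))
})

test_that("size matching picks nearest effective sizes with declared tie-breaks", {
  nodes <- sprintf("G%03d", 1:300)
  net <- build_global_network(data.frame(gene_a = nodes[-300],
                                         gene_b = nodes[-1]))
  mk <- function(id, n) gene_set(id, nodes[seq_len(n)])
  coll <- list(main = list(mk("s010", 10), mk("s048", 48),
                           mk("s052", 52), mk("s200", 200)))
  sel <- select_size_matched_reference(coll, net, target_size = 50,
                                       per_collection = 2)
  expect_setequal(vapply(sel, function(s) s$set_id, character(1)),
                  c("s048", "s052"))

  # equal distance from the target: lexicographically smaller id wins
  tie <- list(main = list(mk("zzz", 48), mk("aaa", 52)))
  one <- select_size_matched_reference(tie, net, target_size = 50,
                                       per_collection = 1)
  expect_equal(one[[1]]$set_id, "aaa")

  small <- list(main = list(mk("a", 10), mk("b", 20), mk("c", 30),
                            mk("d", 40)))
  expect_warning(
    all4 <- select_size_matched_reference(small, net, 25, per_collection = 10),
    "only 4")
  expect_length(all4, 4L)

  # effective size counts only genes present in the network
  ghost <- gene_set("ghost", c(nodes[1:10], sprintf("NOPE%02d", 1:40)))
  coll2 <- list(main = list(ghost, mk("s049", 49)))
  sel2 <- select_size_matched_reference(coll2, net, 50, per_collection = 1)
  expect_equal(sel2[[1]]$set_id, "s049")
})

test_that("reference panels separate planted and random slopes", {
  world <- test_world()
  set.seed(33)
  panel <- suppressMessages(
    build_reference_panel(world$network, world$reference_collections,
                          target_size = 40, n_random = 100))
  expect_lt(panel$beta_min, panel$beta_max)
  expect_equal(panel$beta_min, stats::median(panel$high_slopes))
  expect_equal(panel$beta_max, stats::median(panel$random_slopes))
  expect_length(panel$random_slopes, 100L)

  set.seed(34)
  single <- suppressMessages(
    build_reference_panel(world$network, world$reference_collections,
                          target_size = 40, n_random = 1))
  expect_equal(single$beta_max, single$random_slopes[1])
})

test_that("unusable reference sets trigger the panel error", {
  nodes <- sprintf("G%03d", 1:200)
  net <- build_global_network(data.frame(gene_a = nodes[-200],
                                         gene_b = nodes[-1]))
  # sets entirely absent from the network: no slopes can be fit
  absent <- list(bad = lapply(1:5, function(i)
    gene_set(paste0("x", i), sprintf("NOPE%d_%d", i, 1:20))))
  set.seed(35)
  expect_error(
    suppressMessages(suppressWarnings(
      build_reference_panel(net, absent, 20, n_random = 5))),
    "fewer than 3 usable")
})

test_that("normalization maps the panel anchors to 0 and 1 and is not clamped", {
  panel <- manual_panel(beta_min = 1, beta_max = 5)
  expect_equal(normalize_slope(5, panel), 0)
  expect_equal(normalize_slope(1, panel), 1)
  expect_equal(normalize_slope(2, panel), 0.75)
  # slopes below beta_min give coherence above 1 (legal, not clamped)
  expect_gt(normalize_slope(0.5, panel), 1)

  degenerate <- manual_panel(2, 2)
  expect_error(normalize_slope(1, degenerate), "degenerate")
})

test_that("CI normalization transforms both bounds and reorders them", {
  panel <- manual_panel(beta_min = 1, beta_max = 5)
  fit <- structure(list(beta = 3, ci_low = 1, ci_high = 5, n_points = 10,
                        residual_df = 9), class = "slope_fit")
  expect_equal(unname(normalize_ci(fit, panel)), c(0, 1))

  zero <- structure(list(beta = 5, ci_low = 5, ci_high = 5, n_points = 10,
                         residual_df = 9), class = "slope_fit")
  expect_equal(unname(normalize_ci(zero, panel)), c(0, 0))

  mid <- structure(list(beta = 2, ci_low = 1.5, ci_high = 2.5, n_points = 10,
                        residual_df = 9), class = "slope_fit")
  expect_equal(unname(normalize_ci(mid, panel)), c(0.625, 0.875))
})

test_that("coherence is invariant under a common rescaling of slopes", {
  set.seed(36)
  for (a in c(0.5, 2, 10)) {
    beta <- runif(1, 1, 4)
    p1 <- manual_panel(beta_min = 0.8, beta_max = 4.5)
    p2 <- manual_panel(beta_min = 0.8 * a, beta_max = 4.5 * a)
    expect_equal(normalize_slope(beta, p1), normalize_slope(a * beta, p2))
  }
})

test_that("planted dense modules score near 1 and random queries near 0", {
  world <- test_world()
  high <- world$phenotypes[[1]]
  stopifnot(high$category == "high")
  tab <- compute_degrees(world$network, high)
  g <- nrow(tab)
  set.seed(37)
  panel <- suppressMessages(
    build_reference_panel(world$network, world$reference_collections,
                          target_size = g, n_random = 100))
  fit <- fit_origin_slope(tab)
  expect_gt(normalize_slope(fit$beta, panel), 0.8)

  cohs <- vapply(1:100, function(i) {
    repeat {
      rtab <- compute_degrees(world$network, sample(world$network$nodes, g))
      if (any(rtab$k_int > 0)) break
    }
    normalize_slope(fit_origin_slope(rtab)$beta, panel)
  }, numeric(1))
  expect_lt(abs(mean(cohs)), 0.15)
})
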