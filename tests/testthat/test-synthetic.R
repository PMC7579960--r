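test_that("background generator hits the expected edge count and is seeded", {
  net <- generate_background(1000, density_param = 0.01, seed = 51)
  expected <- 0.01 * choose(1000, 2)
  sdev <- sqrt(choose(1000, 2) * 0.01 * 0.99)
  expect_lt(abs(nrow(net$edges) - expected), 3 * sdev)

  net2 <- generate_background(1000, density_param = 0.01, seed = 51)
  expect_identical(net$edges, net2$edges)
  net3 <- generate_background(1000, density_param = 0.01, seed = 52)
  expect_false(identical(net$edges, net3$edges))

  expect_error(generate_background(50), "at least 100")
})

test_that("preferential-attachment backgrounds are heavy-tailed", {
  net <- generate_background(1000, model = "powerlaw", density_param = 3,
                             seed = 53)
  expect_gt(max(net$degree), 5 * stats::median(net$degree))
})

test_that("a planted perfect clique has zero external edges and slope zero", {
  net <- generate_background(500, density_param = 0.01, seed = 54)
  pm <- plant_module(net, 10, p_in = 1, p_out = 0, fresh_symbols = TRUE)
  tab <- compute_degrees(pm$network, pm$set)
  expect_equal(tab$k_int, rep(9L, 10))
  expect_equal(tab$k_ext, rep(0L, 10))
  expect_identical(fit_origin_slope(tab)$beta, 0)
})

test_that("dense planted modules sit below the random median slope", {
  net <- generate_background(1000, density_param = 0.01, seed = 55)
  set.seed(55)
  pm <- plant_module(net, 30, p_in = 0.9, p_out = 0.01)
  beta <- fit_origin_slope(compute_degrees(pm$network, pm$set))$beta
  random_betas <- vapply(1:50, function(i) {
    repeat {
      tab <- compute_degrees(pm$network, sample(pm$network$nodes, 30))
      if (any(tab$k_int > 0)) return(fit_origin_slope(tab)$beta)
    }
  }, numeric(1))
  expect_lt(beta, stats::median(random_betas))
})

test_that("background-density modules are indistinguishable from random", {
  # keep planted reference modules a tiny fraction of the gene universe so
  # random panel draws are essentially pure background draws
  world <- generate_world(n_genes = 2000, background_p = 0.005,
                          n_collections = 2, modules_per_collection = 3,
                          module_size_range = c(15, 15),
                          phenotype_levels = "random",
                          phenotype_sizes = 20, seed = 56)
  set.seed(56)
  panel <- suppressMessages(suppressWarnings(
    build_reference_panel(world$network, world$reference_collections,
                          target_size = 40, n_random = 100,
                          per_collection = 3)))
  cohs <- vapply(1:50, function(i) {
    pm <- plant_module(world$network, 40, p_in = 0.005, p_out = 0.005,
                       fresh_symbols = TRUE)
    tab <- compute_degrees(pm$network, pm$set)
    if (!any(tab$k_int > 0)) return(NA_real_)
    normalize_slope(fit_origin_slope(tab)$beta, panel)
  }, numeric(1))
  cohs <- cohs[!is.na(cohs)]
  ci_half <- 1.96 * stats::sd(cohs) / sqrt(length(cohs))
  expect_lt(abs(mean(cohs)), ci_half + 0.1)
})

test_that("planted sets are disjoint and symbols follow the naming scheme", {
  world <- small_world(57)
  planted <- c(unlist(lapply(unlist(world$reference_collections,
                                    recursive = FALSE),
                             function(s) s$genes)),
               unlist(lapply(world$phenotypes[
                 vapply(world$phenotypes, function(p) p$category != "random",
                        logical(1))], function(s) s$genes)))
  expect_false(any(duplicated(planted)))
  expect_true(all(grepl("^G\\d{6}$", world$network$nodes)))
})

test_that("worlds round-trip exactly through the on-disk dialects", {
  world <- small_world(58)
  dir <- tempfile()
  set.seed(58)
  paths <- write_world(world, dir)
  edges <- read_string_links(file.path(dir, "links.txt"),
                             score_threshold = 500)
  net <- build_global_network(edges)
  expect_identical(net$nodes, world$network$nodes)
  expect_identical(net$edges, world$network$edges)

  gmts <- list.files(dir, pattern = "\\.gmt$", full.names = TRUE)
  expect_length(gmts, length(world$reference_collections))
  for (p in gmts) {
    cname <- sub("\\.gmt$", "", basename(p))
    sets <- read_gmt(p)
    orig <- world$reference_collections[[cname]]
    expect_length(sets, length(orig))
    for (k in seq_along(sets)) {
      expect_identical(sort(sets[[k]]$genes), sort(orig[[k]]$genes))
    }
  }

  phen <- read_phenotype_table(file.path(dir, "phenotypes.tsv"),
                               category_column = "CATEGORY")
  expect_length(phen, length(world$phenotypes))
  for (k in seq_along(phen)) {
    expect_identical(sort(phen[[k]]$genes), sort(world$phenotypes[[k]]$genes))
    expect_identical(phen[[k]]$category, world$phenotypes[[k]]$category)
  }

  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$params$n_genes, world$params$n_genes)
})

test_that("pipeline coherence recovers the planted ordering across seeds", {
  means <- sapply(1:20, function(sd) {
    world <- generate_world(n_genes = 800, background_p = 0.01,
                            n_collections = 2, modules_per_collection = 5,
                            module_size_range = c(15, 30),
                            phenotype_levels = c("high", "medium", "random"),
                            phenotype_sizes = c(25, 25, 25),
                            seed = 600 + sd)
    set.seed(600 + sd)
    panel <- suppressMessages(suppressWarnings(
      build_reference_panel(world$network, world$reference_collections,
                            target_size = 25, n_random = 50,
                            per_collection = 5)))
    vapply(world$phenotypes, function(ph) {
      tab <- compute_degrees(world$network, ph)
      if (!any(tab$k_int > 0)) return(NA_real_)
      normalize_slope(fit_origin_slope(tab)$beta, panel)
    }, numeric(1))
  })
  avg <- rowMeans(means, na.rm = TRUE)  # high, medium, random
  expect_gt(avg[1], avg[2])
  expect_gt(avg[2], avg[3])
})

test_that("reference sets queried against their own panel score near one", {
  world <- test_world()
  sets <- unlist(world$reference_collections, recursive = FALSE)[1:15]
  panel_cache <- new.env()
  cohs <- vapply(sets, function(s) {
    tab <- compute_degrees(world$network, s)
    g <- nrow(tab)
    key <- as.character(g)
    if (is.null(panel_cache[[key]])) {
      set.seed(59 + g)
      panel_cache[[key]] <- suppressMessages(
        build_reference_panel(world$network, world$reference_collections,
                              target_size = g, n_random = 50))
    }
    normalize_slope(fit_origin_slope(tab)$beta, panel_cache[[key]])
  }, numeric(1))
  expect_lt(abs(stats::median(cohs) - 1), 0.1)
})
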