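test_that("production metric equals the quadruple-loop oracle everywhere", {
  withr::with_seed(101, {
    worst <- 0
    for (rep in 1:60) {
      n <- sample(3:12, 1)
      w <- sample(2:8, 1)
      layers <- random_layers(n, w, p = runif(1, 0.1, 0.6))
      for (iso in c("zero", "skip")) {
        for (den in c("geometric", "product")) {
          got <- temporal_correlation(layers, isolated = iso,
                                      denominator = den)
          want <- naive_temporal_correlation(layers, iso, den)
          worst <- max(worst, max(abs(got - want)))
        }
      }
    }
    expect_lt(worst, 1e-12)
  })
})

test_that("analytic anchors of the temporal correlation hold", {
  # identical non-empty neighbourhoods in every layer: C = 1
  a <- layers_from_edges(4, rep(list(list(c(1, 2), c(3, 4))), 5))
  expect_equal(temporal_correlation(a), rep(1, 4))
  # always-disjoint consecutive neighbourhoods: C = 0
  b <- layers_from_edges(4, list(list(c(1, 2)), list(c(3, 4)), list(c(1, 2))))
  expect_equal(temporal_correlation(b), rep(0, 4))
  # worked 3-node example: edge sets {1-2}, {1-2, 1-3}, {1-3}
  d <- layers_from_edges(3, list(list(c(1, 2)),
                                 list(c(1, 2), c(1, 3)),
                                 list(c(1, 3))))
  expect_equal(temporal_correlation(d)[1], 1 / sqrt(2), tolerance = 1e-12)
  expect_error(temporal_correlation(d[1]), "single window")
})

test_that("the coefficient is bounded in [0,1] and hits 1 only for constant neighbourhoods", {
  withr::with_seed(202, {
    for (rep in 1:40) {
      layers <- random_layers(sample(3:10, 1), sample(2:6, 1), runif(1, 0.2, 0.8))
      ci <- temporal_correlation(layers)
      expect_true(all(ci >= 0 & ci <= 1 + 1e-15))
      # C_i = 1 exactly when every layer repeats a non-empty neighbourhood
      n <- nrow(layers[[1]])
      for (i in seq_len(n)) {
        neigh <- lapply(layers, function(a) which(a[i, ] == 1))
        same <- all(vapply(neigh[-1], identical, logical(1), neigh[[1]])) &&
          length(neigh[[1]]) > 0
        expect_equal(abs(ci[i] - 1) < 1e-12, same)
      }
    }
  })
})

test_that("layer-order reversal leaves every nodal value unchanged", {
  withr::with_seed(303, {
    for (rep in 1:10) {
      layers <- random_layers(6, 5, 0.4)
      expect_equal(temporal_correlation(rev(layers)),
                   temporal_correlation(layers), tolerance = 1e-12)
    }
  })
})

test_that("density averaging and aggregation are plain arithmetic means", {
  one <- matrix(runif(6), 1, 6)
  expect_equal(average_over_densities(one), drop(one))
  two <- rbind(rep(0.2, 3), rep(0.6, 3))
  expect_equal(average_over_densities(two), rep(0.4, 3))
  ones <- matrix(1, 50, 4)
  expect_equal(average_over_densities(ones), rep(1, 4))
  expect_error(average_over_densities(numeric()), "matrix")

  tab <- validate_node_table(tibble::tibble(
    node_index = 0:2, node_label = c("a", "b", "c"),
    network_label = c("visual", "visual", "salience")
  ))
  agg <- aggregate_stability(c(0.2, 0.4, 0.9), tab)
  expect_equal(agg$whole_brain, 0.5)
  expect_equal(agg$per_network[["visual"]], 0.3)
  expect_equal(agg$per_network[["salience"]], 0.9)
  expect_error(aggregate_stability(c(0.1, 0.2), tab), "does not match")
  # constant nodal values propagate to every level
  aggc <- aggregate_stability(rep(0.7, 3), tab)
  expect_equal(unname(aggc$per_network), c(0.7, 0.7))
  expect_equal(aggc$whole_brain, 0.7)
})

test_that("the fused pipeline equals the modular composition at every setting", {
  withr::with_seed(404, {
    n <- 8
    tab <- synthetic_node_table(9)[1:8, ]
    tab <- validate_node_table(tab)
    ts <- subject_time_series(matrix(rnorm(n * 36), n, 36), "s", 1)
    spec <- make_windows(36, 1, 12, 4)
    densities <- c(0.1, 0.25, 0.5)
    for (rank in c("signed", "absolute")) {
      for (iso in c("zero", "skip")) {
        prof <- compute_stability(ts, tab, spec, densities,
                                  rank = rank, isolated = iso)
        nets <- build_dynamic_networks(ts, spec, densities, rank = rank)
        per_density <- t(vapply(nets, temporal_correlation, numeric(n),
                                isolated = iso))
        expect_equal(unname(prof$per_density), unname(per_density),
                     tolerance = 1e-12)
        nodal <- average_over_densities(per_density)
        expect_equal(unname(prof$nodal), unname(nodal), tolerance = 1e-12)
        agg <- aggregate_stability(nodal, tab)
        expect_equal(prof$whole_brain, agg$whole_brain, tolerance = 1e-12)
        expect_equal(prof$per_network, agg$per_network, tolerance = 1e-12)
      }
    }
  })
})

test_that("profile invariants hold: aggregates are means of nodal values", {
  withr::with_seed(505, {
    tab <- synthetic_node_table(12)
    ts <- generate_subject(cohort_config(n_nodes = 12, n_timepoints = 90,
                                         node_table = tab),
                           dwell_global = 20, seed = 9)
    prof <- compute_stability(ts, tab, densities = density_grid(0.05, 0.5, 0.05))
    expect_true(all(prof$per_density >= 0 & prof$per_density <= 1))
    expect_equal(prof$whole_brain, mean(prof$nodal), tolerance = 1e-12)
    for (nw in names(prof$per_network)) {
      expect_equal(prof$per_network[[nw]],
                   mean(prof$nodal[nodes_of_network(tab, nw) + 1]),
                   tolerance = 1e-12)
    }
  })
})

test_that("a periodic series with identical windows is perfectly stable", {
  withr::with_seed(606, {
    ts <- periodic_subject(n_nodes = 5, n_rep = 6, period = 3)
    spec <- make_windows(ncol(ts$data), 1, 6, 3)
    # densities high enough that no node is ever isolated (an isolated
    # node's degenerate terms count as zero overlap and would pull the
    # whole-brain mean below 1 even for identical layers)
    prof <- compute_stability(ts, synthetic_node_table(9)[1:5, ] |>
                                validate_node_table(),
                              spec, densities = c(0.8, 1.0))
    expect_equal(prof$whole_brain, 1, tolerance = 1e-12)
  })
})

test_that("random rewiring between layers degrades stability monotonically", {
  withr::with_seed(707, {
    n <- 20
    base <- random_layers(n, 1, 0.25)[[1]]
    pair_pool <- which(upper.tri(base))
    rewire <- function(a, prob) {
      up <- which(upper.tri(a) & a == 1)
      flip <- up[runif(length(up)) < prob]
      a[flip] <- 0L
      empty <- setdiff(which(upper.tri(a) & a == 0), flip)
      add <- sample(empty, length(flip))
      a[add] <- 1L
      a[lower.tri(a)] <- t(a)[lower.tri(a)]
      a
    }
    probs <- c(0, 0.1, 0.2, 0.35, 0.5)
    mean_c <- vapply(probs, function(p) {
      mean(vapply(1:8, function(r) {
        layers <- vector("list", 6)
        layers[[1]] <- base
        for (t in 2:6) layers[[t]] <- rewire(layers[[t - 1]], p)
        mean(temporal_correlation(layers))
      }, numeric(1)))
    }, numeric(1))
    ct <- suppressWarnings(
      stats::cor.test(probs, mean_c, method = "spearman",
                      alternative = "less")
    )
    expect_lt(ct$estimate, 0)
    expect_lt(ct$p.value, 0.01)
  })
})

test_that("tidy and glance expose the expected tabular views", {
  tab <- synthetic_node_table(10)
  ts <- generate_subject(cohort_config(n_nodes = 10, n_timepoints = 60,
                                       node_table = tab),
                         dwell_global = 15, seed = 2, subject_id = "subA")
  prof <- compute_stability(ts, tab, densities = c(0.2, 0.4))
  td <- tidy(prof)
  expect_setequal(unique(td$level), c("whole_brain", "network", "node"))
  expect_equal(sum(td$level == "node"), 10)
  expect_equal(td$temporal_correlation[td$level == "whole_brain"],
               prof$whole_brain)
  gl <- glance(prof)
  expect_equal(gl$n_nodes, 10)
  expect_equal(gl$subject_id, "subA")
  expect_s3_class(autoplot(prof), "ggplot")
})
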