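test_that("candidate grid spans the positive distance range", {
  withr::with_seed(3, {
    D <- random_distance_matrix(10)
    expect_equal(candidate_radii(D, 1), max(D))
    r <- candidate_radii(D, 50)
    expect_length(r, 50)
    expect_true(all(diff(r) > 0))
    expect_true(all(r > min(D[D > 0])))
    expect_equal(r[50], max(D))
    expect_lt(max(abs(diff(r) - diff(r)[1])), 1e-12)  # even spacing
  })
  expect_error(candidate_radii(matrix(0, 3, 3), 10), "zero")
})

test_that("average degree counts thresholded edges only", {
  D <- as_distance_matrix(as.matrix(dist(cbind(1:4))))
  expect_equal(average_degree(build_neighbor_graph(D, 10)), 3)    # complete
  ng0 <- build_neighbor_graph(D, 1e-6)
  expect_equal(average_degree(ng0), 0)                            # empty
  # borrowed MST edges do not count toward the degree filter
  ngc <- connect_graph(ng0, D)
  expect_gt(ngc$n_mst_edges, 0)
  expect_equal(average_degree(ngc), 0)

  withr::with_seed(37, {
    D <- random_distance_matrix(12)
    ng <- build_neighbor_graph(D, 0.4)
    per_node <- rowSums(D < 0.4 & D > 0 |
                          (D == 0 & row(D) != col(D))) # direct recount
    expect_equal(average_degree(ng), mean(per_node))
  })
})

test_that("objective correlation is 1 for exactly embeddable geometries", {
  line <- as_distance_matrix(as.matrix(dist(cbind(c(0, 1, 2.5, 4)))))
  expect_equal(objective_correlation(line), 1, tolerance = 1e-8)
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(objective_correlation(as_distance_matrix(tri)), 1,
               tolerance = 1e-8)

  withr::with_seed(43, {
    D <- random_distance_matrix(12)
    params <- lmdist_params()
    got <- objective_correlation(D, params)
    # independent pipeline: oracle PCoA -> dims by variance -> Euclidean ->
    # Pearson
    or <- pcoa_oracle(D)
    ve <- or$eigenvalues / sum(or$eigenvalues)
    nd <- min(which(cumsum(ve) > 0.8)[1], 10, length(ve))
    ed <- as.matrix(dist(or$coordinates[, seq_len(nd), drop = FALSE]))
    expect_equal(got, cor(ed[upper.tri(ed)], D[upper.tri(D)]),
                 tolerance = 1e-8)
  })

  # regular simplex: constant distances but an exact embedding
  flat <- matrix(1, 4, 4); diag(flat) <- 0
  expect_equal(objective_correlation(as_distance_matrix(flat)), 1)
  # truly degenerate: all samples identical, no positive eigenvalue
  zero <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(z <- objective_correlation(zero), "degenerate")
  expect_equal(z, 0)
})

test_that("the incumbent rule prefers large radii unless beaten by epsilon", {
  rule <- lmdist:::choose_radius_index
  radius <- seq(0.1, 1, by = 0.1)
  valid <- rep(TRUE, 10)

  # flat correlations: largest radius wins
  expect_equal(rule(radius, rep(0.9, 10), valid, 0.05), 10)
  # planted mid-grid winner just above the margin
  corr <- rep(0.90, 10); corr[5] <- 0.96
  expect_equal(rule(radius, corr, valid, 0.05), 5)
  # the same winner below the margin loses
  corr[5] <- 0.949
  expect_equal(rule(radius, corr, valid, 0.05), 10)
  # invalid radii are never chosen, whatever their correlation
  corr[5] <- 1.0; valid[5] <- FALSE
  expect_equal(rule(radius, corr, valid, 0.05), 10)
  expect_equal(rule(radius, corr, rep(FALSE, 10), 0.05), NA_integer_)
  # the incumbent updates: successive small improvements each > epsilon
  corr <- c(rep(0, 7), 0.30, 0.18, 0.05)
  expect_equal(rule(radius, corr, rep(TRUE, 10), 0.1), 8)
  # epsilon = 0: argmax, largest radius among ties
  corr <- c(0.2, 0.8, 0.8, 0.5, rep(0.1, 6))
  expect_equal(rule(radius, corr, rep(TRUE, 10), 0), 3)
  # epsilon = Inf: always the largest valid radius
  expect_equal(rule(radius, corr, rep(TRUE, 10), Inf), 10)
})

test_that("select_radius's choice is re-derivable from its diagnostics", {
  withr::with_seed(53, {
    comm <- simulate_coenocline_community(
      coenocline_params(n_samples = 30, gradient_length = 600,
                        center_margin = 400))
    D <- bray_curtis(comm$table)
    params <- lmdist_params(n_radii = 12, epsilon = 0.01)
    res <- select_radius(D, params)
    dg <- res$diagnostics
    expect_equal(nrow(dg), 12)
    expect_true(all(dg$degree_valid ==
                      (dg$average_degree >= params$phi * nrow(D))))
    # replay the rule independently, descending over the grid
    best <- NA; best_cor <- -Inf
    for (k in order(dg$radius, decreasing = TRUE)) {
      if (!dg$degree_valid[k]) next
      if (is.na(best) || dg$objective_correlation[k] > best_cor +
            params$epsilon) {
        best <- k; best_cor <- dg$objective_correlation[k]
      }
    }
    expect_equal(res$chosen_radius, dg$radius[best])
    expect_true(dg$degree_valid[best])
    # the returned matrix is the fixed-radius transform at the winner
    expect_equal(res$adjusted, lmdist_fixed_radius(D, res$chosen_radius))
  })
})

test_that("no valid radius or tiny inputs mean no adjustment", {
  D <- as_distance_matrix(as.matrix(dist(cbind(c(0, 1, 3)))))
  expect_warning(res <- select_radius(D), "fewer than 4")
  expect_null(res$chosen_radius)
  expect_equal(res$adjusted, D)

  # phi too demanding for n = 4: every radius fails the degree filter
  D4 <- as_distance_matrix(as.matrix(dist(cbind(c(0, 1, 2, 4)))))
  res4 <- select_radius(D4, lmdist_params(phi = 0.9, n_radii = 8))
  expect_null(res4$chosen_radius)
  expect_equal(res4$adjusted, D4)
  expect_false(any(res4$diagnostics$degree_valid))
})

test_that("gaussian smoothing is a convex combination centered correctly", {
  withr::with_seed(59, {
    A <- random_distance_matrix(6)
    B <- A * 1.5
    expect_equal(gaussian_smooth(list(A), 0.5, 0.5, 0.1), A)
    # sigma -> 0: delta at the chosen radius
    expect_equal(gaussian_smooth(list(A, B), c(0.4, 0.8), 0.8, 1e-12), B)
    # equal matrices: sigma irrelevant
    expect_equal(gaussian_smooth(list(A, A), c(0.4, 0.8), 0.4, 0.3), A)
    # convexity bounds
    S <- gaussian_smooth(list(A, B), c(0.4, 0.8), 0.6, 0.2)
    expect_true(all(S >= pmin(A, B) - 1e-12 & S <= pmax(A, B) + 1e-12))
    expect_error(gaussian_smooth(list(), numeric(0), 0.5, 0.1), "no adjusted")
  })
})

test_that("lmdist_auto smoothing minimally alters the chosen-radius result", {
  withr::with_seed(61, {
    comm <- simulate_coenocline_community(
      coenocline_params(n_samples = 30, gradient_length = 600,
                        center_margin = 400))
    D <- bray_curtis(comm$table)
    plain <- lmdist_auto(D, lmdist_params(n_radii = 15))
    smoothed <- lmdist_auto(D, lmdist_params(n_radii = 15, smooth = TRUE))
    expect_false(plain$smoothed)
    expect_true(smoothed$smoothed)
    expect_equal(plain$chosen_radius, smoothed$chosen_radius)
    expect_lt(max(abs(plain$adjusted - smoothed$adjusted)) /
                max(plain$adjusted), 0.25)
  })
})
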