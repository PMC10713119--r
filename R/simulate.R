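#' Parameters of the coenocline gradient simulator
#'
#' Defaults describe a community sampled evenly along a gradient of length
#' 1000 (arbitrary units): species response curves are Gaussian coenoclines
#' with centers every 10 units and a common standard deviation of 150, wide
#' enough for heavy overlap between neighboring species. Centers extend
#' `center_margin` units beyond both gradient ends so edge samples see a
#' full species pool; with the defaults that makes
#' `(1000 + 2*650)/10 + 1 = 231` features for 50 samples.
#'
#' @param gradient_length length of the environmental gradient (default
#'   1000, arbitrary units).
#' @param center_spacing distance between neighboring species optima
#'   (default 10).
#' @param sd standard deviation of every Gaussian coenocline (default 150).
#' @param n_samples number of evenly spaced samples (default 50).
#' @param center_margin how far species centers extend beyond each gradient
#'   end (default 650).
#' @param noise_replicates Dirichlet noise replicates per base sample
#'   (default 1).
#' @param dirichlet_scale concentration multiplier for the Dirichlet noise
#'   (default 500); larger values keep noise samples closer to their parent
#'   composition.
#' @param seed integer seed for the Dirichlet draws, or `NULL`.
#' @return an object of class `coenocline_params`.
#' @export
coenocline_params <- function(gradient_length = 1000, center_spacing = 10,
                              sd = 150, n_samples = 50, center_margin = 650,
                              noise_replicates = 1, dirichlet_scale = 500,
                              seed = NULL) {
  stopifnot(gradient_length > 0, center_spacing > 0, sd > 0,
            n_samples >= 2, center_margin >= 0,
            noise_replicates >= 0, dirichlet_scale > 0)
  structure(list(gradient_length = gradient_length,
                 center_spacing = center_spacing, sd = sd,
                 n_samples = as.integer(n_samples),
                 center_margin = center_margin,
                 noise_replicates = as.integer(noise_replicates),
                 dirichlet_scale = dirichlet_scale, seed = seed),
            class = "coenocline_params")
}

#' Simulate a gradient community from Gaussian coenoclines
#'
#' Each species' abundance at gradient position x is the value of its
#' Gaussian response curve (density of N(center, sd) at x); each sample
#' collects every species' response at its position, then is closed to
#' relative abundances (the absolute curve heights are arbitrary). Samples
#' sit evenly over the full gradient. This is deterministic — noise is
#' added separately by [add_dirichlet_noise()].
#'
#' @param params a [coenocline_params()] object.
#' @return an object of class `simulated_community`: list with `table`
#'   (samples x features relative abundances, rows sum to 1), `positions`
#'   (gradient coordinate per sample), and `is_noise` (all `FALSE` here).
#' @examples
#' comm <- simulate_coenocline_community(coenocline_params())
#' dim(comm$table)  # 50 x 231
#' @export
simulate_coenocline_community <- function(params = coenocline_params()) {
  stopifnot(inherits(params, "coenocline_params"))
  centers <- seq(-params$center_margin,
                 params$gradient_length + params$center_margin,
                 by = params$center_spacing)
  if (length(centers) < 2)
    stop("margin and spacing give fewer than 2 species; widen the pool")
  pos <- seq(0, params$gradient_length, length.out = params$n_samples)
  tab <- vapply(centers, function(cc) dnorm(pos, mean = cc, sd = params$sd),
                numeric(length(pos)))
  tab <- tab / rowSums(tab)
  rownames(tab) <- sprintf("S%03d", seq_len(nrow(tab)))
  colnames(tab) <- sprintf("F%03d", seq_along(centers))
  structure(list(table = tab, positions = pos,
                 is_noise = rep(FALSE, nrow(tab))),
            class = "simulated_community")
}

#' @export
print.simulated_community <- function(x, ...) {
  cat(sprintf("simulated community: %d samples (%d noise) x %d features\n",
              nrow(x$table), sum(x$is_noise), ncol(x$table)))
  invisible(x)
}

#' Add compositional noise replicates from a Dirichlet distribution
#'
#' Each base sample's composition, scaled by `dirichlet_scale`, becomes the
#' concentration vector of a Dirichlet distribution from which
#' `noise_replicates` noisy compositions are drawn (via the standard
#' gamma-normalization construction). Noise samples inherit the parent's
#' gradient position, are flagged `is_noise = TRUE`, and are placed
#' immediately before their parent in row order. Concentrations are floored
#' at 1e-12 so species far from a sample's position cannot produce
#' zero-concentration failures.
#'
#' @param community a `simulated_community` of base samples.
#' @param params a [coenocline_params()] object; `seed`, `dirichlet_scale`
#'   and `noise_replicates` are used.
#' @return a `simulated_community` with `n_samples * (1 + noise_replicates)`
#'   rows.
#' @export
add_dirichlet_noise <- function(community, params = coenocline_params()) {
  stopifnot(inherits(community, "simulated_community"),
            inherits(params, "coenocline_params"))
  if (params$noise_replicates == 0) return(community)
  if (!is.null(params$seed)) set.seed(params$seed)
  base <- community$table
  nf <- ncol(base)
  rows <- list(); posv <- numeric(0); noisev <- logical(0); labs <- character(0)
  for (i in seq_len(nrow(base))) {
    alpha <- pmax(params$dirichlet_scale * base[i, ], 1e-12)
    for (r in seq_len(params$noise_replicates)) {
      g <- rgamma(nf, shape = alpha, rate = 1)
      if (sum(g) == 0) g[which.max(alpha)] <- 1   # guard against underflow
      rows[[length(rows) + 1L]] <- g / sum(g)
      posv <- c(posv, community$positions[i])
      noisev <- c(noisev, TRUE)
      labs <- c(labs, sprintf("%s_noise%d", rownames(base)[i], r))
    }
    rows[[length(rows) + 1L]] <- base[i, ]
    posv <- c(posv, community$positions[i])
    noisev <- c(noisev, community$is_noise[i])
    labs <- c(labs, rownames(base)[i])
  }
  tab <- do.call(rbind, rows)
  dimnames(tab) <- list(labs, colnames(base))
  structure(list(table = tab, positions = posv, is_noise = noisev),
            class = "simulated_community")
}

#' Swiss-roll benchmark point cloud
#'
#' Standard parametrization: with u, v uniform on \[0, 1\], the roll angle
#' is t = 1.5 pi (1 + 2 u) and a point is (t cos t, 21 v, t sin t). The
#' intrinsic (unrolled) coordinates are (t, 21 v). A classic test of
#' whether a method recovers distances along a curled 2-D manifold embedded
#' in 3-D.
#'
#' @param n number of points (>= 10).
#' @param seed integer seed, or `NULL`.
#' @return list with `coordinates` (n x 3, columns x/y/z) and `intrinsic`
#'   (n x 2, columns t/height).
#' @export
swiss_roll <- function(n = 300, seed = NULL) {
  stopifnot(n >= 10)
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n)
  v <- runif(n)
  t <- 1.5 * pi * (1 + 2 * u)
  coords <- cbind(x = t * cos(t), y = 21 * v, z = t * sin(t))
  rownames(coords) <- sprintf("P%03d", seq_len(n))
  intrinsic <- cbind(t = t, height = 21 * v)
  rownames(intrinsic) <- rownames(coords)
  list(coordinates = coords, intrinsic = intrinsic)
}
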