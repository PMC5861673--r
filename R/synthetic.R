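#' Synthetic dataset specification
#'
#' Defines the conditions under which synthetic leaves are generated: the
#' model variant, per-variable uniform sampling ranges (defaulting to the
#' fitting bounds of the model variant), additive measurement noise, an
#' optional chlorophyll-carotenoid coupling, and a single seed controlling
#' all stochasticity.
#'
#' @param n_leaves Number of leaves, `>= 1`.
#' @param version Model version (a `"b"` suffix enables brown pigments).
#' @param brown Logical; draw a nonzero brown pigment content.
#' @param ranges Named list of `c(min, max)` per active variable;
#'   defaults to the fitting bounds. Must lie within them.
#' @param noise_sigma Standard deviation of the i.i.d. Gaussian noise added
#'   to each reflectance value (default 0.005, the order of magnitude of
#'   the measurement-chain residual).
#' @param coupling `NULL`, or `list(ratio =, jitter =)`: for versions that
#'   separate pigments, draw `Cc = Cab / ratio + noise(jitter)` truncated
#'   at zero, emulating the strong chlorophyll-carotenoid correlation of
#'   real leaves (content ratio about 5).
#' @param seed Integer seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_leaves, version = "PD", brown = FALSE,
                            ranges = NULL, noise_sigma = 0.005,
                            coupling = NULL, seed = 1L) {
  pv <- .parse_version(version, brown)
  stopifnot(n_leaves >= 1, noise_sigma >= 0, is.numeric(seed))
  active <- active_variables(pv$version, pv$brown)
  b <- default_bounds()
  full <- lapply(active, function(v) c(b$lower[[v]], b$upper[[v]]))
  names(full) <- active
  if (!is.null(ranges)) {
    for (nm in names(ranges)) {
      if (!nm %in% active)
        stop("range given for inactive variable ", nm)
      r <- ranges[[nm]]
      if (length(r) != 2 || r[1] > r[2]) stop("empty range for ", nm)
      if (r[1] < b$lower[[nm]] - 1e-12 || r[2] > b$upper[[nm]] + 1e-12)
        stop("range for ", nm, " exceeds the fitting bounds")
      full[[nm]] <- as.numeric(r)
    }
  }
  if (!is.null(coupling)) {
    stopifnot(is.list(coupling), all(c("ratio", "jitter") %in%
                                       names(coupling)),
              coupling$ratio > 0, coupling$jitter >= 0)
    if (!all(c("Cab", "Cc") %in% active))
      stop("pigment coupling requires a version separating Cab and Cc")
  }
  structure(list(n_leaves = as.integer(n_leaves), version = pv$version,
                 brown = pv$brown, ranges = full,
                 noise_sigma = noise_sigma, coupling = coupling,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Draw ground-truth parameter vectors
#'
#' Uniform draws within the configured ranges for every active variable
#' (inactive variables zero, `N` at least 1). With coupling enabled, the
#' carotenoid content follows the chlorophyll content with Gaussian jitter,
#' truncated at zero and at its upper range. Deterministic given the seed.
#'
#' @param spec A [simulation_spec()].
#' @return A list of [leaf_params()] of length `n_leaves`.
#' @export
sample_params <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_leaves
  draws <- lapply(spec$ranges, function(r) stats::runif(n, r[1], r[2]))
  if (!is.null(spec$coupling)) {
    cc <- draws$Cab / spec$coupling$ratio +
      stats::rnorm(n, 0, spec$coupling$jitter)
    draws$Cc <- pmin(pmax(cc, 0), spec$ranges$Cc[2])
  }
  lapply(seq_len(n), function(i) {
    args <- lapply(draws, `[[`, i)
    do.call(leaf_params, args)
  })
}

#' Generate a synthetic leaf dataset with known ground truth
#'
#' Forward-simulates each drawn parameter vector through the full
#' white-background system, adds i.i.d. Gaussian noise per wavelength,
#' truncates to `[0, 1]`, and returns the samples together with the true
#' parameters. Leaves are alternately tagged with the pigment or the
#' water/dry-matter destructive subset (filled from the ground truth), so a
#' written bundle exercises the same reader path as real data.
#'
#' @param spec A [simulation_spec()].
#' @param coefs A [coefficient_set] for `spec$version`.
#' @param bg Background spectrum or scalar.
#' @return A list with `samples` (list of [leaf_sample()]), `truth`
#'   (data.frame of true parameters, one row per leaf) and `params` (the
#'   list of true [leaf_params()]).
#' @export
generate_dataset <- function(spec, coefs = synthetic_coefficients(
                               spec$version),
                             bg = background_spectrum(coefs$grid)) {
  stopifnot(inherits(spec, "simulation_spec"),
            inherits(coefs, "coefficient_set"))
  if (coefs$version != spec$version)
    stop("coefficient set version does not match the simulation spec")
  params <- sample_params(spec) # seeds the RNG; noise draws follow
  rwb <- .bg_values(bg, coefs)
  wl <- coefs$wavelength
  samples <- vector("list", spec$n_leaves)
  for (i in seq_along(params)) {
    p <- params[[i]]
    r <- .system_reflectance_vec(coefs, rwb, unlist(p[names(coefs$sac)]),
                                 p$N, p$Rsurf, p$fwb)
    if (spec$noise_sigma > 0)
      r <- r + stats::rnorm(length(r), 0, spec$noise_sigma)
    r <- pmin(pmax(r, 0), 1)
    id <- sprintf("synth_%03d", i)
    pig <- i %% 2 == 1
    truthC <- unlist(p)
    dest <- if (pig) {
      if (all(c("Cab", "Cc") %in% names(coefs$sac)))
        list(Cab = truthC[["Cab"]], Cc = truthC[["Cc"]])
      else # pooled versions have no separate reference chemistry; split by
        # the canonical 5:1 content ratio for bookkeeping
        list(Cab = truthC[["Cabc"]] * 5 / 6, Cc = truthC[["Cabc"]] / 6)
    } else {
      list(Cw = truthC[["Cw"]], Cm = truthC[["Cm"]])
    }
    samples[[i]] <- leaf_sample(id, spectrum(wl, r), dest,
                                sample_id = ceiling(i / 6),
                                stage = "two_nodes_april",
                                cultivar = "synthetic",
                                modality = "synthetic")
  }
  names(samples) <- vapply(samples, `[[`, character(1), "leaf_id")
  truth <- do.call(rbind, lapply(seq_along(params), function(i)
    data.frame(leaf_id = samples[[i]]$leaf_id,
               t(unlist(params[[i]])), row.names = NULL)))
  list(samples = samples, truth = truth, params = params)
}
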