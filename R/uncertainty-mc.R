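#' Distribution specification for Monte Carlo inputs
#'
#' One stochastic (or fixed) model input. Supported kinds and their
#' parameters:
#' * `point`: `value`
#' * `uniform`: `min`, `max`
#' * `normal`: `mean`, `sd`
#' * `lognormal`: `meanlog`, `sdlog` (natural-log scale)
#' * `triangular`: `min`, `mode`, `max`
#'
#' Optional truncation to `[lo, hi]` is applied by inverse-CDF restriction
#' (the distribution is renormalised on the interval), so no draws are
#' rejected and reproducibility is exact.
#'
#' @param kind Distribution kind (see above).
#' @param ... Kind-specific parameters, named.
#' @param truncation Optional numeric `c(lo, hi)`, `lo < hi`.
#' @return Object of class `cr_dist`.
#' @export
dist_spec <- function(kind = c("point", "uniform", "normal", "lognormal",
                               "triangular"),
                      ..., truncation = NULL) {
  kind <- match.arg(kind)
  params <- list(...)
  need <- switch(kind,
                 point = "value",
                 uniform = c("min", "max"),
                 normal = c("mean", "sd"),
                 lognormal = c("meanlog", "sdlog"),
                 triangular = c("min", "mode", "max"))
  missing_p <- setdiff(need, names(params))
  if (length(missing_p) > 0) {
    stop_config("dist_spec(%s): missing parameter(s) %s", kind,
                paste(missing_p, collapse = ", "))
  }
  params <- params[need]
  if (!all(vapply(params, function(v)
    is.numeric(v) && length(v) == 1 && is.finite(v), logical(1)))) {
    stop_config("dist_spec(%s): parameters must be finite scalars", kind)
  }
  ok <- switch(kind,
               point = TRUE,
               uniform = params$min < params$max,
               normal = params$sd > 0,
               lognormal = params$sdlog > 0,
               triangular = params$min <= params$mode &&
                 params$mode <= params$max && params$min < params$max)
  if (!ok) stop_config("dist_spec(%s): invalid parameters", kind)
  if (!is.null(truncation)) {
    if (length(truncation) != 2 || any(is.na(truncation)) ||
        truncation[1] >= truncation[2]) {  # infinite one-sided bounds allowed
      stop_config("truncation must be c(lo, hi) with lo < hi")
    }
    if (kind == "point" && (params$value < truncation[1] ||
                            params$value > truncation[2])) {
      stop_config("point value lies outside its truncation interval")
    }
  }
  structure(list(kind = kind, params = params, truncation = truncation),
            class = "cr_dist")
}

# CDF / quantile of the untruncated distribution.
.dist_p <- function(d, q) {
  p <- d$params
  switch(d$kind,
         point = as.numeric(q >= p$value),
         uniform = stats::punif(q, p$min, p$max),
         normal = stats::pnorm(q, p$mean, p$sd),
         lognormal = stats::plnorm(q, p$meanlog, p$sdlog),
         triangular = .ptri(q, p$min, p$mode, p$max))
}

.dist_q <- function(d, u) {
  p <- d$params
  switch(d$kind,
         point = rep(p$value, length(u)),
         uniform = stats::qunif(u, p$min, p$max),
         normal = stats::qnorm(u, p$mean, p$sd),
         lognormal = stats::qlnorm(u, p$meanlog, p$sdlog),
         triangular = .qtri(u, p$min, p$mode, p$max))
}

.ptri <- function(q, a, c, b) {
  out <- numeric(length(q))
  q <- pmin(pmax(q, a), b)
  left <- q <= c
  if (c > a) out[left] <- (q[left] - a)^2 / ((b - a) * (c - a))
  out[!left] <- 1 - (b - q[!left])^2 / ((b - a) * (b - c))
  out
}

.qtri <- function(u, a, c, b) {
  fc <- (c - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

#' Draw from a distribution specification
#'
#' Uses the current RNG stream (set the seed with `set.seed()` or via
#' [mc_spec()]/[run_mc()]). Truncated draws map uniforms through the CDF
#' restricted to the truncation interval, so truncation never discards
#' draws.
#'
#' @param dist A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(dist, n) {
  stopifnot(inherits(dist, "cr_dist"), n >= 0)
  if (dist$kind == "point" && is.null(dist$truncation)) {
    return(rep(dist$params$value, n))
  }
  u <- stats::runif(n)
  if (!is.null(dist$truncation)) {
    plo <- .dist_p(dist, dist$truncation[1])
    phi <- .dist_p(dist, dist$truncation[2])
    if (phi - plo <= 0) stop_config("truncation interval has zero mass")
    u <- plo + u * (phi - plo)
  }
  .dist_q(dist, u)
}

#' Monte Carlo run specification
#'
#' @param n_iter Iterations (default 10000, the conventional choice for
#'   probabilistic health-risk assessment).
#' @param seed Integer seed; the whole run uses one seeded RNG stream with a
#'   fixed iteration order, so results are reproducible and independent of
#'   any parallel scheduling.
#' @param params Named list of [dist_spec()]s: keys are `"cn"` or any
#'   numeric [receptor_profile()] field (`IngR`, `InhR`, `SA`, `AF`, `ABS`,
#'   `EF`, `ED`, `BW`, `AT`, `PEF`).
#' @return Object of class `cr_mc_spec`.
#' @export
mc_spec <- function(n_iter = 10000, seed = 1, params = list()) {
  if (!is.numeric(n_iter) || n_iter < 1) {
    stop_config("mc_spec: n_iter must be >= 1")
  }
  if (length(params) > 0) {
    if (is.null(names(params)) || any(names(params) == "")) {
      stop_config("mc_spec: params must be a named list")
    }
    ok <- vapply(params, inherits, logical(1), what = "cr_dist")
    if (!all(ok)) stop_config("mc_spec: every param must be a dist_spec()")
    allowed <- c("cn", "IngR", "InhR", "SA", "AF", "ABS", "EF", "ED",
                 "BW", "AT", "PEF")
    bad <- setdiff(names(params), allowed)
    if (length(bad) > 0) {
      stop_config("mc_spec: unknown parameter(s) %s", paste(bad, collapse = ", "))
    }
  }
  structure(list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                 params = params), class = "cr_mc_spec")
}

#' Monte Carlo propagation of uncertainty through the hazard-quotient model
#'
#' Every iteration draws each stochastic parameter from its distribution,
#' evaluates the deterministic hazard-quotient model, and collects the total
#' HQ. Parameters without a distribution keep their point value from `p`
#' (or `cn`). Identical spec and seed give identical results; with all
#' distributions point masses the summary collapses exactly onto the
#' deterministic HQ. Percentiles use the median-unbiased quantile estimator
#' (`type = 8`).
#'
#' @param cn Point soil concentration, mg/kg (ignored if `mc$params$cn` is
#'   given).
#' @param p A [receptor_profile()] of point values.
#' @param tox A [toxicity_params()].
#' @param mc An [mc_spec()].
#' @param pathways Pathways included in the total HQ.
#' @param store_draws Keep the per-iteration parameter draws (needed by
#'   [rank_sensitivity()]).
#' @return Object of class `cr_mc`: list with `group`, `n_iter`, `seed`,
#'   `mean`, `sd`, `p5`, `p50`, `p95`, `prob_exceed_1`, and (optionally)
#'   `draws` (data frame of parameter draws plus `hq_total`).
#' @export
run_mc <- function(cn, p, tox = toxicity_params(), mc = mc_spec(),
                   pathways = c("ing", "derm", "inh"), store_draws = FALSE) {
  stopifnot(inherits(p, "cr_receptor"), inherits(mc, "cr_mc_spec"))
  if (mc$n_iter < 100) {
    warning("n_iter < 100: percentile estimates will be unstable")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(mc$seed)

  n <- mc$n_iter
  stochastic <- names(mc$params)
  draws <- list()
  for (nm in stochastic) draws[[nm]] <- sample_dist(mc$params[[nm]], n)

  p_iter <- unclass(p)
  for (nm in intersect(stochastic, names(p_iter))) p_iter[[nm]] <- draws[[nm]]
  class(p_iter) <- "cr_receptor"
  cn_iter <- if ("cn" %in% stochastic) draws[["cn"]] else rep(cn, n)

  hq <- hazard_quotients(cn_iter, p_iter, tox, pathways = pathways)$hq_total
  qs <- stats::quantile(hq, c(0.05, 0.5, 0.95), type = 8, names = FALSE)
  out <- list(group = p$group, n_iter = n, seed = mc$seed,
              mean = mean(hq), sd = stats::sd(hq),
              p5 = qs[1], p50 = qs[2], p95 = qs[3],
              prob_exceed_1 = mean(hq > 1))
  if (store_draws) {
    out$draws <- if (length(draws) > 0) {
      data.frame(draws, hq_total = hq, check.names = FALSE)
    } else {
      data.frame(hq_total = hq)
    }
  }
  structure(out, class = "cr_mc")
}

#' @export
print.cr_mc <- function(x, ...) {
  cat(sprintf("Monte Carlo HQ, group %s: %d iterations (seed %d)\n",
              x$group, x$n_iter, x$seed))
  cat(sprintf("  mean %.4g  sd %.4g\n", x$mean, x$sd))
  cat(sprintf("  p5 %.4g  p50 %.4g  p95 %.4g\n", x$p5, x$p50, x$p95))
  cat(sprintf("  P(HQ > 1) = %.4f\n", x$prob_exceed_1))
  invisible(x)
}

#' @export
summary.cr_mc <- function(object, ...) {
  data.frame(group = object$group, n_iter = object$n_iter, seed = object$seed,
             mean = object$mean, sd = object$sd, p5 = object$p5,
             p50 = object$p50, p95 = object$p95,
             prob_exceed_1 = object$prob_exceed_1, stringsAsFactors = FALSE)
}

#' Rank-correlation sensitivity of the Monte Carlo HQ
#'
#' Spearman correlation of each stochastic parameter's draws with the total
#' HQ, ordered by decreasing `|rho|` — the standard companion analysis of
#' spreadsheet Monte Carlo tools. Requires a [run_mc()] result created with
#' `store_draws = TRUE`.
#'
#' @param mc_result A `cr_mc` object with stored draws.
#' @return Data frame with columns `parameter`, `rho`, sorted by `|rho|`.
#' @export
rank_sensitivity <- function(mc_result) {
  stopifnot(inherits(mc_result, "cr_mc"))
  if (is.null(mc_result$draws)) {
    stop_input("run_mc() must be called with store_draws = TRUE")
  }
  params <- setdiff(names(mc_result$draws), "hq_total")
  params <- params[vapply(params, function(nm)
    stats::sd(mc_result$draws[[nm]]) > 0, logical(1))]
  if (length(params) == 0) {
    warning("no stochastic parameters; nothing to rank")
    return(data.frame(parameter = character(0), rho = numeric(0)))
  }
  rho <- vapply(params, function(nm)
    stats::cor(mc_result$draws[[nm]], mc_result$draws$hq_total,
               method = "spearman"), numeric(1))
  out <- data.frame(parameter = params, rho = unname(rho),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$rho)), , drop = FALSE]
}
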