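# Thermodynamics of oxidative phosphorylation as a two-flow linear energy
# converter: the degree of coupling q links the leak-dominated resting
# respiration (state 4o) to the phosphorylating flux (state 3), and the
# optimal efficiency is a function of q alone.

#' Optimal thermodynamic efficiency from the degree of coupling
#'
#' For a two-flow linear energy converter with coupling degree `q`, the
#' efficiency at the optimal-efficiency force ratio
#' \eqn{x_{opt} = -q/(1 + \sqrt{1-q^2})} is
#' \deqn{\eta_{opt} = q^2 / (1 + \sqrt{1 - q^2})^2.}
#' It is continuous and strictly increasing on \[0, 1\] with
#' \eqn{\eta_{opt}(0) = 0} and \eqn{\eta_{opt}(1) = 1}.
#'
#' @param q numeric vector of coupling degrees in `[0, 1]`.
#' @return numeric vector of optimal efficiencies in `[0, 1]`.
#' @export
eta_opt <- function(q) {
  if (any(q < 0 | q > 1, na.rm = TRUE)) stop("q must lie in [0, 1]")
  s <- sqrt(pmax(0, 1 - q^2))
  q^2 / (1 + s)^2
}

#' Degree of thermodynamic coupling from respiration states
#'
#' State 4o (oligomycin-inhibited, proton-leak) respiration is taken as the
#' zero-output fraction of the phosphorylating state 3 flux, giving
#' \eqn{q = \sqrt{1 - state4o / state3}}. At zero offset this coincides
#' with \eqn{\sqrt{1 - 1/RCR}}.
#'
#' @param state3,state4o aligned numeric vectors (same offset-adjusted
#'   scale as used for the RCR).
#' @param q_policy what to do when `state4o > state3` (q undefined):
#'   `"clamp"` sets q = 0 and records a warning flag; `"strict"` errors.
#' @return numeric vector of q values in `[0, 1]`, with attribute
#'   `"clamped"` (logical vector) under the clamp policy.
#' @export
coupling_degree <- function(state3, state4o, q_policy = c("clamp", "strict")) {
  q_policy <- match.arg(q_policy)
  stopifnot(length(state3) == length(state4o))
  if (any(state3 <= 0, na.rm = TRUE))
    stop("state3 must be positive (apply the batch offset first)")
  ratio <- state4o / state3
  bad <- ratio > 1
  if (any(bad, na.rm = TRUE)) {
    if (q_policy == "strict")
      stop("state4o > state3 for ", sum(bad, na.rm = TRUE),
           " sample(s): q undefined under strict policy")
    ratio[bad] <- 1
  }
  q <- sqrt(pmax(0, 1 - ratio))
  attr(q, "clamped") <- !is.na(bad) & bad
  q
}

#' Respiratory control ratio with the batch offset rule
#'
#' RCR = state 3 / state 4o. When any state 4o reading in the batch is
#' non-positive (plate traces can go negative after antimycin-range
#' corrections), a single constant
#' \eqn{c = -\min(state4o) + \epsilon} is added to *all* state 3 and
#' state 4o readings of the batch before taking the ratio; `c = 0` when
#' all state 4o are positive. The applied offset is always reported.
#'
#' @param state3,state4o aligned numeric vectors.
#' @param epsilon positive offset margin; default 1% of the median state 3.
#' @return list with `rcr` (per-sample ratios), `offset` (the constant c),
#'   `state3_adj`, `state4o_adj` (offset-adjusted values) and
#'   `flagged_low` (logical, RCR < 1 i.e. state3 < state4o).
#' @export
respiratory_control_ratio <- function(state3, state4o, epsilon = NULL) {
  stopifnot(length(state3) == length(state4o))
  if (is.null(epsilon)) epsilon <- 0.01 * stats::median(state3, na.rm = TRUE)
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("epsilon must be positive")
  m <- min(state4o, na.rm = TRUE)
  c_off <- if (m > 0) 0 else -m + epsilon
  s3 <- state3 + c_off
  s4 <- state4o + c_off
  if (any(s4 <= 0, na.rm = TRUE))
    stop("internal error: state4o still non-positive after offset")
  list(rcr = s3 / s4, offset = c_off,
       state3_adj = s3, state4o_adj = s4,
       flagged_low = !is.na(s3) & !is.na(s4) & s3 < s4)
}

#' Coupling analysis of a batch of respiration states
#'
#' Computes, per sample: the respiratory control ratio (with the batch
#' offset rule), the coupling degree q (from the offset-adjusted states,
#' so q and RCR refer to the same numbers), the optimal efficiency, and
#' the Stucki set-point band of q.
#'
#' @inheritParams respiratory_control_ratio
#' @inheritParams coupling_degree
#' @param sample optional sample identifiers.
#' @param setpoints a [stucki_setpoints()] object.
#' @return A data frame of class `coupling_result` with columns `sample`,
#'   `rcr`, `offset`, `q`, `eta_opt`, `band`, `q_clamped`, `rcr_below_1`.
#' @export
thermodynamic_coupling <- function(state3, state4o, sample = NULL,
                                   epsilon = NULL,
                                   q_policy = c("clamp", "strict"),
                                   setpoints = stucki_setpoints()) {
  q_policy <- match.arg(q_policy)
  if (is.null(sample)) sample <- seq_along(state3)
  rc <- respiratory_control_ratio(state3, state4o, epsilon)
  q <- coupling_degree(rc$state3_adj, rc$state4o_adj, q_policy)
  out <- data.frame(sample = sample,
                    rcr = rc$rcr,
                    offset = rc$offset,
                    q = as.numeric(q),
                    eta_opt = eta_opt(as.numeric(q)),
                    band = classify_coupling(as.numeric(q), setpoints),
                    q_clamped = attr(q, "clamped"),
                    rcr_below_1 = rc$flagged_low,
                    stringsAsFactors = FALSE)
  class(out) <- c("coupling_result", "data.frame")
  out
}

#' Converter output functions at the optimal-efficiency force ratio
#'
#' \eqn{F_n(q) = q^n s / (1+s)^n} with \eqn{s = \sqrt{1-q^2}}:
#' n = 1 net output flow, 2 output power, 3 economic flow (flow times
#' efficiency), 4 economic power. The maxima of these four functions
#' over q define the Stucki set points.
#'
#' @param q coupling degree(s) in `[0, 1]`. @param n output-function
#'   order, 1-4.
#' @return numeric vector of output-function values.
#' @export
stucki_output_fn <- function(q, n) {
  s <- sqrt(pmax(0, 1 - q^2))
  q^n * s / (1 + s)^n
}

.stucki_cache <- new.env(parent = emptyenv())

#' Stucki set points of the degree of coupling
#'
#' The four q values at which optimal efficiency coincides with maximal
#' net output flow (q_f), output power (q_p), economic flow (q_f_ec) and
#' economic power (q_p_ec). Each is the argmax over q in (0, 1) of
#' \eqn{F_n(q) = q^n s/(1+s)^n}, \eqn{s = \sqrt{1-q^2}}, n = 1..4,
#' found by bracketed scalar maximization (not hard-coded). Results are
#' cached per tolerance after first derivation.
#'
#' @param tolerance optimizer tolerance in `(0, 1e-3]`.
#' @return object of class `stucki_setpoints`: list with `q_f`, `q_p`,
#'   `q_f_ec`, `q_p_ec` and `x_opt` (the optimal-efficiency force ratio
#'   \eqn{-q/(1+s)} at each set point).
#' @export
stucki_setpoints <- function(tolerance = 1e-8) {
  if (!is.finite(tolerance) || tolerance <= 0 || tolerance > 1e-3)
    stop("tolerance must lie in (0, 1e-3]")
  key <- format(tolerance, digits = 17)
  if (!is.null(.stucki_cache[[key]])) return(.stucki_cache[[key]])
  qs <- vapply(1:4, function(n) {
    opt <- stats::optimize(stucki_output_fn, interval = c(1e-9, 1 - 1e-9),
                           n = n, maximum = TRUE, tol = tolerance)
    # unimodality guard: the maximum must beat both bracket ends
    ends <- stucki_output_fn(c(1e-9, 1 - 1e-9), n)
    if (opt$objective <= max(ends))
      stop("set-point optimizer failed the bracket check for n = ", n)
    opt$maximum
  }, numeric(1))
  s <- sqrt(1 - qs^2)
  out <- structure(list(q_f = qs[1], q_p = qs[2],
                        q_f_ec = qs[3], q_p_ec = qs[4],
                        x_opt = -qs / (1 + s)),
                   class = "stucki_setpoints")
  .stucki_cache[[key]] <- out
  out
}

#' @export
print.stucki_setpoints <- function(x, ...) {
  cat("Stucki set points (degree of coupling q):\n")
  cat(sprintf("  q_f    (max net output flow)   = %.3f\n", x$q_f))
  cat(sprintf("  q_p    (max output power)      = %.3f\n", x$q_p))
  cat(sprintf("  q_f_ec (max economic flow)     = %.3f\n", x$q_f_ec))
  cat(sprintf("  q_p_ec (max economic power)    = %.3f\n", x$q_p_ec))
  invisible(x)
}

#' Classify coupling degrees against the Stucki set points
#'
#' Bands are half-open `[lower, upper)` intervals between consecutive set
#' points.
#'
#' @param q numeric vector in `[0, 1]`.
#' @param setpoints a [stucki_setpoints()] object.
#' @return character vector with levels `"below q_f"`, `"q_f-q_p"`,
#'   `"q_p-q_f_ec"`, `"q_f_ec-q_p_ec"`, `"above q_p_ec"`.
#' @export
classify_coupling <- function(q, setpoints = stucki_setpoints()) {
  if (any(q < 0 | q > 1, na.rm = TRUE)) stop("q must lie in [0, 1]")
  breaks <- c(-Inf, setpoints$q_f, setpoints$q_p, setpoints$q_f_ec,
              setpoints$q_p_ec, Inf)
  labels <- c("below q_f", "q_f-q_p", "q_p-q_f_ec", "q_f_ec-q_p_ec",
              "above q_p_ec")
  as.character(cut(q, breaks = breaks, labels = labels, right = FALSE))
}
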