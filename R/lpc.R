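# Linear predictive coding of PSSM column signals: autocorrelation-method LPC
# solved by the Levinson-Durbin recursion, one coefficient block per
# (residue column, model order).

#' Biased autocorrelation sequence
#'
#' r(k) = sum_t s_t * s_(t+k) for k = 0..max_lag (no 1/L normalization; the
#' LPC normal equations are invariant to a common scale on r).
#'
#' @param signal Numeric vector.
#' @param max_lag Largest lag (>= 0), at most `length(signal) - 1`.
#' @return Numeric vector of length `max_lag + 1` (lags 0..max_lag).
#' @export
autocorr_sequence <- function(signal, max_lag) {
  L <- length(signal)
  stopifnot(max_lag >= 0, max_lag <= L - 1)
  vapply(0:max_lag, function(k) {
    sum(signal[seq_len(L - k)] * signal[seq_len(L - k) + k])
  }, numeric(1))
}

# Levinson-Durbin recursion on r(0..p); returns a_1..a_p of the forward
# predictor s_t ~ sum_k a_k s_(t-k). If the recursion breaks down (prediction
# error reaches zero, e.g. a perfectly predictable constant column), r(0) is
# regularized by +1e-10 and the solve retried once.
levinson_durbin <- function(r, p, .regularized = FALSE) {
  if (r[[1]] == 0) return(numeric(p))
  a <- numeric(p)
  err <- r[[1]]
  for (m in seq_len(p)) {
    acc <- r[[m + 1]]
    if (m > 1) acc <- acc - sum(a[seq_len(m - 1)] * r[m:2])
    if (err <= .Machine$double.eps * abs(r[[1]])) {
      if (.regularized) {
        stop("Levinson-Durbin breakdown persists after regularization",
             call. = FALSE)
      }
      r2 <- r
      r2[[1]] <- r2[[1]] + 1e-10
      return(levinson_durbin(r2, p, .regularized = TRUE))
    }
    k <- acc / err
    a_new <- a
    a_new[[m]] <- k
    if (m > 1) {
      a_new[seq_len(m - 1)] <- a[seq_len(m - 1)] - k * a[(m - 1):1]
    }
    a <- a_new
    err <- err * (1 - k^2)
  }
  a
}

#' LPC predictor coefficients of a signal
#'
#' Fits the order-`p` autoregressive predictor of the autocorrelation method,
#' s_t ~ a_1 s_(t-1) + ... + a_p s_(t-p), by the Levinson-Durbin recursion on
#' the biased autocorrelation estimate. The gain/error term is not returned;
#' the feature block for order p has exactly p entries.
#'
#' @param signal Numeric vector of length L >= p + 1.
#' @param order Positive integer model order p.
#' @return Numeric vector `a` of length `order`. If r(0) = 0 (all-zero
#'   signal), the zero vector.
#' @export
#' @examples
#' lpc_coefficients(sin(0.4 * (0:49)), 3)
lpc_coefficients <- function(signal, order) {
  stopifnot(is.numeric(signal), length(order) == 1, order >= 1)
  order <- as.integer(order)
  L <- length(signal)
  if (L < order + 1) {
    stop("sequence too short for order ", order, ": need length >= ",
         order + 1, ", got ", L, call. = FALSE)
  }
  if (anyNA(signal) || any(!is.finite(signal))) {
    stop("signal contains non-finite values", call. = FALSE)
  }
  r <- autocorr_sequence(signal, order)
  levinson_durbin(r, order)
}

#' LPC order configuration
#'
#' @param orders Strictly increasing positive integers; the default
#'   `3:10` is the lpc3..lpc10 set whose 20-column encoding yields a
#'   1040-dimensional block.
#' @return Integer vector of class `lpc_config`.
#' @export
lpc_config <- function(orders = 3:10) {
  orders <- as.integer(orders)
  if (length(orders) == 0 || any(orders < 1) || is.unsorted(orders, strictly = TRUE)) {
    stop("`orders` must be strictly increasing positive integers", call. = FALSE)
  }
  structure(orders, class = "lpc_config")
}

#' Dimension of the PSSM LPC feature block
#'
#' @param orders LPC orders (vector or [lpc_config()]).
#' @return Integer: 20 * sum(orders).
#' @export
lpc_block_dim <- function(orders = lpc_config()) {
  20L * sum(as.integer(orders))
}

#' Encode a normalized PSSM as an LPC feature block
#'
#' For each of the 20 residue columns (in [aa_alphabet()] order) and each
#' model order p in `orders`, appends the p LPC predictor coefficients of
#' that column's positional signal. Block layout is residue-major, then
#' order, then coefficient index; names follow
#' `pssm_<residue>_p<order>_a<k>`.
#'
#' @param npssm A `normalized_pssm` from [sigmoid_normalize()].
#' @param orders LPC orders (vector or [lpc_config()]); default `3:10`.
#' @return Named numeric vector of length `20 * sum(orders)`.
#' @export
encode_pssm_lpc <- function(npssm, orders = lpc_config()) {
  stopifnot(inherits(npssm, "normalized_pssm"))
  orders <- lpc_config(as.integer(orders))
  pmax_ <- max(orders)
  if (npssm$L < pmax_ + 1) {
    stop("PSSM too short for LPC orders: need at least ", pmax_ + 1,
         " positions for max order ", pmax_, ", got ", npssm$L, call. = FALSE)
  }
  aa <- aa_alphabet()
  out <- vector("list", 20L * length(orders))
  idx <- 0L
  for (j in seq_len(20)) {
    # the autocorrelation sequence up to the largest order is shared by all
    # orders of this column
    r <- autocorr_sequence(npssm$values[, j], pmax_)
    for (p in as.integer(orders)) {
      idx <- idx + 1L
      out[[idx]] <- levinson_durbin(r[seq_len(p + 1)], p)
    }
  }
  v <- unlist(out, use.names = FALSE)
  names(v) <- unlist(lapply(aa, function(res) {
    unlist(lapply(as.integer(orders), function(p) {
      paste0("pssm_", res, "_p", p, "_a", seq_len(p))
    }))
  }))
  v
}
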