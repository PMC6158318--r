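#' Precision-modulated likelihood mapping
#'
#' Applies the inferred sensory precision `zeta` to a likelihood array as a
#' temperature: every conditional outcome distribution (column) is replaced by
#' the column-wise softmax of `zeta * log A`, i.e.
#' `Abar_ij = A_ij^zeta / sum_k A_kj^zeta`. `zeta = 1` returns `A` unchanged,
#' `zeta = 0` flattens every column to uniform (observations carry no
#' information), and large `zeta` drives every column to a delta on its argmax
#' (a deterministic likelihood).
#'
#' `zeta` may be a vector indexed by the levels of one parent factor (per
#' fixation-location precision): pass `along` to say which parent dimension of
#' `A` selects the component.
#'
#' @param A Likelihood array (or [likelihood_mapping()]), columns stochastic.
#' @param zeta Non-negative precision scalar, or vector with one entry per
#'   level of parent dimension `along`.
#' @param along Parent dimension (1 = first parent) whose level selects the
#'   precision component; required when `zeta` is a vector.
#' @param eps Probability floor used inside the logarithm.
#' @return Array of the same shape with column-stochastic entries.
#' @examples
#' A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2)
#' modulate_likelihood(A, 1)   # = A
#' modulate_likelihood(A, 0)   # uniform columns
#' modulate_likelihood(A, 50)  # deterministic columns
#' @export
modulate_likelihood <- function(A, zeta, along = NULL, eps = 1e-16) {
  if (inherits(A, "likelihood_mapping")) A <- A$A
  A <- as.array(A)
  if (any(zeta < 0) || any(!is.finite(zeta))) {
    stop("modulate_likelihood(): zeta must be finite and >= 0", call. = FALSE)
  }
  lnA <- log_stable(A, eps)
  dims <- dim(A)
  n_out <- dims[1]
  if (length(zeta) == 1) {
    zcol <- rep(zeta, prod(dims[-1]))
  } else {
    if (is.null(along)) {
      stop("modulate_likelihood(): vector zeta needs 'along'", call. = FALSE)
    }
    pd <- dims[-1]
    if (length(zeta) != pd[along]) {
      stop("modulate_likelihood(): length(zeta) != levels of parent dim ",
           along, call. = FALSE)
    }
    # zeta per column, replicated over the other parent dims
    idx <- slice.index(array(0, dim = pd), along)
    zcol <- zeta[as.vector(idx)]
  }
  m <- matrix(lnA, nrow = n_out)
  m <- sweep(m, 2, zcol, `*`)
  m <- exp(sweep(m, 2, apply(m, 2, max), `-`))
  cs <- colSums(m)
  if (any(cs <= 0)) {
    stop("modulate_likelihood(): a column vanished after modulation",
         call. = FALSE)
  }
  array(sweep(m, 2, cs, `/`), dim = dims, dimnames = dimnames(A))
}

#' Predicted outcome distribution under state beliefs
#'
#' Marginalizes a (modulated) likelihood array over factorized state beliefs:
#' `o = Abar . s`, contracting every parent dimension with that factor's
#' belief vector.
#'
#' @param Abar Likelihood array (possibly precision modulated).
#' @param beliefs A probability vector (single parent) or list of probability
#'   vectors, one per parent dimension in order.
#' @return Probability vector over outcomes.
#' @export
predicted_outcomes <- function(Abar, beliefs) {
  if (inherits(Abar, "likelihood_mapping")) Abar <- Abar$A
  if (!is.list(beliefs)) beliefs <- list(beliefs)
  beliefs <- lapply(beliefs, function(b) as.numeric(b))
  o <- ttv_except(as.array(Abar), c(list(NA), beliefs), keep = 1L)
  normalize(o)
}

#' Negative entropy of a likelihood mapping (ambiguity)
#'
#' For each combination of parent state levels `i`,
#' `H_i = sum_j Abar_ji * log(Abar_ji)` over the modality's outcomes: the
#' negative conditional entropy of the outcome given the state. All entries
#' are `<= 0`; the expected ambiguity `-H . s >= 0` enters the expected free
#' energy as the cost of sampling states whose outcomes remain noisy.
#'
#' @param Abar Likelihood array (possibly precision modulated).
#' @param eps Probability floor inside the logarithm.
#' @return Array over the parent dimensions (a vector for a single parent).
#' @examples
#' ambiguity(diag(2))                      # c(0, 0)
#' ambiguity(matrix(rep(1 / 3, 3), 3, 1))  # -log(3)
#' @export
ambiguity <- function(Abar, eps = 1e-16) {
  if (inherits(Abar, "likelihood_mapping")) Abar <- Abar$A
  Abar <- as.array(Abar)
  H <- apply(Abar, seq_along(dim(Abar))[-1],
             function(col) sum(col * log_stable(col, eps)))
  pd <- dim(Abar)[-1]
  if (length(pd) > 1) array(H, dim = pd) else as.numeric(H)
}
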