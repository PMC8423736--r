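#' Log10-transform an abundance matrix
#'
#' Applies the working-scale transform \code{log10(x + 1)} entrywise, so zero
#' abundances stay at zero and the descriptor formulas below operate on
#' corrected (log-scale) abundances.
#'
#' @param a Numeric matrix or vector of non-negative abundances.
#' @return Object of the same shape with transformed values.
#' @export
transform_abundance <- function(a) {
  if (any(a < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative")
  }
  log10(a + 1)
}

#' Pairwise behavioral descriptor of a microbe-microbe interaction
#'
#' Computes one of four closed-form descriptors for an ordered pair of
#' transformed abundances, where \code{xu} belongs to the more abundant
#' member (\code{xu > xv > 0}):
#' \itemize{
#'   \item mutualism:  \eqn{x_u x_v / (x_u - x_v)}
#'   \item antagonism: \eqn{1 / ((x_u x_v)(x_u - x_v))}
#'   \item aggression: \eqn{x_u / x_v}
#'   \item altruism:   \eqn{1 - x_v / x_u}
#' }
#' Pairs with \code{xu == xv} have a vanishing denominator and are undefined:
#' the function returns \code{NA_real_} for them (callers exclude such pairs).
#'
#' @param xu,xv Transformed abundances; \code{xu} is the larger.
#' @param type One of \code{"mutualism"}, \code{"antagonism"},
#'   \code{"aggression"}, \code{"altruism"}.
#' @return Descriptor value, or \code{NA_real_} when undefined.
#' @export
pair_descriptor <- function(xu, xv, type = c("mutualism", "antagonism",
                                             "aggression", "altruism")) {
  type <- match.arg(type)
  if (any(xv <= 0) || any(xu < xv)) {
    stop("require xu >= xv > 0; caller orders the pair")
  }
  out <- switch(type,
    mutualism  = xu * xv / (xu - xv),
    antagonism = 1 / ((xu * xv) * (xu - xv)),
    aggression = xu / xv,
    altruism   = 1 - xv / xu
  )
  out[xu == xv] <- NA_real_
  out
}

interaction_types <- function() {
  c("mutualism", "antagonism", "aggression", "altruism")
}

#' Per-host interaction matrix
#'
#' For a single host's vector of transformed OTU abundances, evaluates the
#' chosen descriptor for every unordered pair with distinct positive
#' abundances. The value is stored at \code{[u, v]} where \code{u} is the more
#' abundant member; all other cells (diagonal, ties, zero-abundance partners,
#' the mirrored position) are \code{NA}.
#'
#' @param x Numeric vector of m transformed abundances (m >= 2), optionally
#'   named by OTU id.
#' @param type Interaction type (see [pair_descriptor()]).
#' @return m x m matrix with attributes \code{type} and \code{scale = "raw"}.
#' @export
interaction_matrix <- function(x, type = c("mutualism", "antagonism",
                                           "aggression", "altruism")) {
  type <- match.arg(type)
  m <- length(x)
  if (m < 2) stop("need at least 2 OTUs")
  xu <- matrix(x, m, m)            # row value  = candidate u
  xv <- t(xu)                      # col value  = candidate v
  valid <- xu > xv & xv > 0        # strict: ties and zeros excluded
  M <- matrix(NA_real_, m, m, dimnames = list(names(x), names(x)))
  M[valid] <- switch(type,
    mutualism  = (xu * xv / (xu - xv))[valid],
    antagonism = (1 / ((xu * xv) * (xu - xv)))[valid],
    aggression = (xu / xv)[valid],
    altruism   = (1 - xv / xu)[valid]
  )
  attr(M, "type") <- type
  attr(M, "scale") <- "raw"
  M
}

#' Min-max normalize an interaction matrix to [0, 1]
#'
#' Rescales the defined entries of one matrix by \code{(z - min)/(max - min)}.
#' A degenerate range (max == min, including a single defined entry) maps all
#' entries to 0. An empty matrix passes through unchanged.
#'
#' @param M Raw-scale interaction matrix from [interaction_matrix()].
#' @return Matrix of the same shape, attribute \code{scale = "normalized"}.
#' @export
normalize_matrix <- function(M) {
  v <- M[!is.na(M)]
  out <- M
  if (length(v) > 0) {
    rng <- range(v)
    if (rng[2] > rng[1]) {
      out[!is.na(out)] <- (v - rng[1]) / (rng[2] - rng[1])
    } else {
      out[!is.na(out)] <- 0
    }
  }
  attr(out, "type") <- attr(M, "type")
  attr(out, "scale") <- "normalized"
  out
}

#' Default retention threshold per interaction type
#'
#' 0.95 for mutualism, antagonism and aggression; 0.99 for altruism.
#' @param type Interaction type.
#' @return Threshold in (0, 1).
#' @export
default_tau <- function(type) {
  switch(match.arg(type, interaction_types()),
    mutualism = 0.95, antagonism = 0.95, aggression = 0.95, altruism = 0.99
  )
}

#' Threshold a normalized interaction matrix into a sparse edge set
#'
#' Retains entries strictly greater than \code{tau}. Row index of a retained
#' entry is the more abundant member of the pair.
#'
#' @param M Normalized interaction matrix.
#' @param tau Retention threshold in (0, 1); defaults to the type's shipped
#'   value (see [default_tau()]).
#' @return data.frame with columns \code{u}, \code{v} (integer indices; OTU id
#'   columns \code{u_id}/\code{v_id} when M has dimnames) and \code{weight};
#'   attributes \code{type}, \code{tau}, \code{m}.
#' @export
threshold_matrix <- function(M, tau = NULL) {
  type <- attr(M, "type")
  if (is.null(tau)) tau <- default_tau(type)
  if (!is.numeric(tau) || tau <= 0 || tau >= 1) {
    stop("tau must lie in (0, 1)")
  }
  if (!identical(attr(M, "scale"), "normalized")) {
    stop("threshold_matrix expects a normalized matrix")
  }
  keep <- which(!is.na(M) & M > tau, arr.ind = TRUE)
  sp <- data.frame(
    u = as.integer(keep[, 1]),
    v = as.integer(keep[, 2]),
    weight = M[keep]
  )
  if (!is.null(rownames(M))) {
    sp$u_id <- rownames(M)[sp$u]
    sp$v_id <- colnames(M)[sp$v]
  }
  sp <- sp[order(sp$u, sp$v), , drop = FALSE]
  rownames(sp) <- NULL
  attr(sp, "type") <- type
  attr(sp, "tau") <- tau
  attr(sp, "m") <- nrow(M)
  sp
}

#' Full descriptor path for one host
#'
#' transform is assumed done by the caller; runs
#' \code{interaction_matrix -> normalize_matrix -> threshold_matrix}.
#'
#' @param x Transformed abundance vector.
#' @inheritParams interaction_matrix
#' @inheritParams threshold_matrix
#' @return Sparse edge data.frame (see [threshold_matrix()]).
#' @export
sparse_interactions <- function(x, type, tau = NULL) {
  threshold_matrix(normalize_matrix(interaction_matrix(x, type)), tau)
}
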