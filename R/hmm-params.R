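#' Parameters of a Poisson hidden Markov model
#'
#' Container for the parameters of a K-state hidden Markov chain with
#' Poisson-distributed window counts: initial state distribution `pi`,
#' row-stochastic transition matrix `A`, and per-state Poisson means
#' `lambda` (expected asynchrony events per window). States are
#' conventionally ordered by increasing `lambda`, so state 1 is the
#' lowest-risk regime and state K the highest.
#'
#' @param pi Initial state distribution (non-negative, sums to 1).
#' @param A K x K transition matrix; each row sums to 1.
#' @param lambda Per-state Poisson means, all strictly positive.
#' @param reorder If `TRUE` (default), relabel states so `lambda` is
#'   increasing; `pi` and `A` are permuted consistently. Set to `FALSE` to
#'   keep a caller-supplied labelling.
#' @return An object of class `hmm_params`.
#' @examples
#' p <- hmm_params(
#'   pi = c(0.52, 0.28, 0.14, 0.06),
#'   A = make_persistent_matrix(c(0.52, 0.28, 0.14, 0.06), 0.85),
#'   lambda = c(1, 11, 38, 119)
#' )
#' p
#' @export
hmm_params <- function(pi, A, lambda, reorder = TRUE) {
  pi <- as.numeric(pi)
  lambda <- as.numeric(lambda)
  A <- as.matrix(A)
  K <- length(lambda)
  if (length(pi) != K || nrow(A) != K || ncol(A) != K) {
    stop("`pi`, `lambda` and the dimensions of `A` must agree on K", call. = FALSE)
  }
  if (any(!is.finite(pi)) || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("`pi` must be a probability vector summing to 1", call. = FALSE)
  }
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("all Poisson means `lambda` must be > 0", call. = FALSE)
  }
  if (any(!is.finite(A)) || any(A < 0) || any(abs(rowSums(A) - 1) > 1e-8)) {
    stop("`A` must be row-stochastic (rows sum to 1, entries >= 0)", call. = FALSE)
  }
  if (reorder) {
    ord <- order(lambda)
    pi <- pi[ord]
    lambda <- lambda[ord]
    A <- A[ord, ord, drop = FALSE]
  }
  structure(
    list(K = K, pi = pi, A = unname(A), lambda = lambda),
    class = "hmm_params"
  )
}

#' @export
print.hmm_params <- function(x, digits = 3, ...) {
  cat("Poisson HMM parameters (K = ", x$K, " states)\n", sep = "")
  cat("lambda:", format(x$lambda, digits = digits), "\n")
  cat("pi:    ", format(x$pi, digits = digits), "\n")
  cat("A:\n")
  print(round(x$A, digits))
  invisible(x)
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of `A` for eigenvalue 1, normalised to sum to 1.
#'
#' @param A Row-stochastic matrix.
#' @return Numeric probability vector.
#' @export
stationary_distribution <- function(A) {
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Write / read a fitted model as JSON
#'
#' The JSON layout is `{"K":…, "pi":[…], "A":[[…]], "lam":[…],
#' "T_minutes":…}`. Numbers are written at full precision so a
#' write/read round trip reproduces the parameters bit-exactly.
#'
#' @param params An [hmm_params] object.
#' @param path File path.
#' @param T_minutes Window length in minutes the model was fitted at.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns an [hmm_params] with attribute
#'   `T_minutes`.
#' @export
write_model_json <- function(params, path, T_minutes = 15) {
  stopifnot(inherits(params, "hmm_params"))
  obj <- list(
    K = params$K,
    pi = params$pi,
    A = apply(params$A, 1, identity, simplify = FALSE),
    lam = params$lambda,
    T_minutes = T_minutes
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- if (is.matrix(obj$A)) obj$A else matrix(unlist(obj$A), nrow = obj$K, byrow = TRUE)
  p <- hmm_params(pi = obj$pi, A = A, lambda = obj$lam, reorder = FALSE)
  attr(p, "T_minutes") <- obj$T_minutes
  p
}

# internal: coerce user data (vector, or data frame with a `count` column and
# optional `patient_id`) to a named list of non-negative integer sequences.
as_count_sequences <- function(data) {
  if (is.data.frame(data)) {
    if (!"count" %in% names(data)) {
      stop("`data` must contain a `count` column", call. = FALSE)
    }
    id_col <- intersect(c("patient_id", "sequence", "id"), names(data))[1]
    if (!is.na(id_col)) {
      seqs <- split(data$count, factor(data[[id_col]], levels = unique(data[[id_col]])))
    } else {
      seqs <- list(`1` = data$count)
    }
  } else if (is.numeric(data)) {
    seqs <- list(`1` = data)
  } else if (is.list(data)) {
    seqs <- data
    if (is.null(names(seqs))) names(seqs) <- seq_along(seqs)
  } else {
    stop("`data` must be a numeric vector, data frame or list of sequences", call. = FALSE)
  }
  seqs <- lapply(seqs, function(x) {
    x <- as.numeric(x)
    if (length(x) == 0) stop("empty count sequence", call. = FALSE)
    if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x))) {
      stop("counts must be non-negative integers", call. = FALSE)
    }
    x
  })
  seqs
}
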