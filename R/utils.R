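# Internal helpers: seeding, argument checks.

#' @importFrom stats rnorm runif quantile fft cor sd qf pf cor.test var
NULL

# Evaluate `expr` under a given RNG seed without clobbering the caller's RNG
# state.  seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Counter-based substream derivation: reproducible, order-independent, and
# keeps every derived seed inside the 32-bit integer range.
derive_seed <- function(master, index, stream = 0L) {
  m <- as.double(master) %% 2147483647
  ((m * 69069 + as.double(index) * 1000003 + as.double(stream) * 97561) %%
     2147483629) + 1
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  x
}

check_alpha <- function(alpha) {
  stopifnot_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly between 0 and 1", call. = FALSE)
  alpha
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

# Coerce a panel argument to a list of N x T matrices (one per trial).
as_trial_list <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    trials <- x
  } else if (is.array(x) && length(dim(x)) == 3L) {
    trials <- lapply(seq_len(dim(x)[3L]), function(r) x[, , r, drop = TRUE])
  } else if (is.matrix(x)) {
    trials <- list(x)
  } else if (is.numeric(x)) {
    trials <- list(matrix(x, nrow = 1L))
  } else {
    stop("panel must be an N x T matrix, an N x T x trials array, ",
         "or a list of N x T matrices", call. = FALSE)
  }
  n <- vapply(trials, nrow, 1L)
  if (length(unique(n)) != 1L)
    stop("all trials must have the same number of nodes", call. = FALSE)
  if (any(!vapply(trials, function(m) all(is.finite(m)), TRUE)))
    stop("panel contains non-finite values", call. = FALSE)
  trials
}
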