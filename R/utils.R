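#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG state, restoring the caller's state afterwards.
# seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministically derive k child seeds from one master seed.
spawn_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_square_symmetric <- function(w, what = "weight matrix", tol = 1e-8) {
  if (!is.matrix(w) || nrow(w) != ncol(w))
    stop_domain(what, " must be a square matrix")
  if (max(abs(w - t(w))) > tol * max(1, max(abs(w))))
    stop_domain(what, " must be symmetric")
  invisible(w)
}

upper_pairs <- function(n) which(upper.tri(matrix(0, n, n)))

# Canonical form of a membership vector: modules renumbered 1,2,... in order
# of first appearance, so label-permuted partitions compare equal.
canonical_membership <- function(m) {
  match(m, unique(m))
}

titlecase <- function(x) {
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}
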