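# Internal helpers shared across modules.

# Round half away from zero, the convention used for printed fold changes.
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_input <- function(...) stop(..., call. = FALSE)

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_input(sprintf("'%s' must be a single positive number", name))
  }
  invisible(x)
}

check_prob <- function(x, name, open_right = FALSE) {
  bad <- !is.numeric(x) || anyNA(x) || any(x < 0) ||
    (if (open_right) any(x >= 1) else any(x > 1))
  if (bad) stop_input(sprintf("'%s' must lie in [0,%s]", name, if (open_right) "1)" else "1"))
  invisible(x)
}

# Canonical (lexicographic) ordering of an unordered gene pair.
canonical_pair <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}

# Two-level group handling: first level (factor order or first appearance)
# is the reference ("ctrl") condition.
split_groups <- function(groups, n_samples) {
  if (length(groups) != n_samples) {
    stop_input("'groups' must have one label per sample")
  }
  lev <- if (is.factor(groups)) levels(droplevels(groups)) else unique(as.character(groups))
  if (length(lev) != 2L) stop_input("exactly two groups are required")
  g <- as.character(groups)
  list(ref = lev[1L], alt = lev[2L], ref_idx = which(g == lev[1L]), alt_idx = which(g == lev[2L]))
}
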