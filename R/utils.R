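`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a run seed and a salt
#'
#' Keeps derived seeds inside the 32-bit integer range so they are always
#' valid arguments to [set.seed()].
#'
#' @param seed Integer run seed.
#' @param salt Integer distinguishing the consumer (gene index, replicate, ...).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, salt) {
  # Lehmer-style mix in double precision; 2147483647 = 2^31 - 1 (prime)
  s <- (as.double(seed) %% 2147483647) * 48271 + (as.double(salt) + 1) * 16807
  as.integer(s %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Stratified sample of size m without replacement, preserving class balance.
# labels in {-1, +1}; guarantees >= 1 sample of each class when possible.
stratified_sample <- function(labels, m) {
  idx_pos <- which(labels == 1L)
  idx_neg <- which(labels == -1L)
  m_pos <- max(1L, min(length(idx_pos), round(m * length(idx_pos) / length(labels))))
  m_neg <- max(1L, min(length(idx_neg), m - m_pos))
  sort(c(
    idx_pos[sample.int(length(idx_pos), m_pos)],
    idx_neg[sample.int(length(idx_neg), m_neg)]
  ))
}

# Deterministic stratified fold assignment (1..k) for labels in {-1, +1}.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in c(-1L, 1L)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
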