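# Deterministic seed derivation.  All randomness in the package flows from
# one user-visible seed; per-task seeds are derived by hashing a task name
# (e.g. the canonical sorted domain-pair id) together with the global seed,
# so per-pair results do not depend on the order pairs are processed in.

MOD31 <- 2147483647  # 2^31 - 1, keeps derived seeds valid R integers

hash_string <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% MOD31
  h
}

#' Derive a reproducible sub-seed from a global seed and a label
#'
#' @param seed Integer global seed.
#' @param label Character label naming the random substream (for example a
#'   canonical domain-pair id).
#' @return An integer in \code{[0, 2^31 - 2]}, usable with [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  as.integer((as.double(seed) %% MOD31 * 48271 +
                hash_string(paste(label, collapse = "\r"))) %% MOD31)
}

pair_seed <- function(seed, id_a, id_b) {
  ids <- sort(c(id_a, id_b))
  derive_seed(seed, paste(ids[1L], ids[2L], sep = "\r"))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_rng_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}
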