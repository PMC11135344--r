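# Deterministic stream of derived seeds: every source of randomness in the
# package is seeded from a user seed through this map, so whole analyses are
# reproducible from one integer.  Result always lies in [1, 2^31 - 2].
.derive_seed <- function(seed, i, salt = 0L) {
  v <- (as.double(seed) %% 1000003) * 8191 +
    as.double(i) * 131071 + as.double(salt) * 524287
  as.integer(v %% 2147483629) + 1L
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
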