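#' @title Reproducible seeding
#' @name seeds
#' @description All stochastic steps take explicit integer seeds. Generators
#'   evaluate their randomness inside [with_seed()], which restores the
#'   caller's RNG state afterwards, so pipeline results never depend on what
#'   the session did before. Per-stage, per-species sub-seeds are derived
#'   from the master seed by a stable string hash, which makes every species
#'   result independent of the order of the species list.
NULL

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the previous global RNG
#' state (including "no state yet").
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Stable string hash
#'
#' Deterministic polynomial hash of the concatenated arguments, independent
#' of R session, platform and load order. Used to derive sub-seeds.
#'
#' @param ... values pasted together (with a separator) and hashed.
#' @return integer in `[0, 2^31 - 2]`.
#' @export
stable_hash <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "\x1f")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Derive a per-stage sub-seed from the master seed
#'
#' @param master master integer seed.
#' @param stage stage name (e.g. `"pseudo_absence"`).
#' @param species_id species label (optional).
#' @return integer seed below `2^31`.
#' @export
sub_seed <- function(master, stage, species_id = "") {
  as.integer((as.numeric(master) * 1000003 +
                stable_hash(stage, species_id)) %% 2147483563)
}
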