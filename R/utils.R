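# shared helpers: residue alphabet, seed derivation, small validators

#' The 20-residue amino-acid alphabet used throughout the package
#' @format character vector of length 20, alphabetical one-letter codes.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# residue string -> integer codes 1..20 (error on anything else)
aa_to_int <- function(s) {
  x <- match(strsplit(s, "", fixed = TRUE)[[1]], AA20)
  if (anyNA(x)) stop("sequence contains non-standard residues: ", s)
  x
}

int_to_aa <- function(x) paste(AA20[x], collapse = "")

#' Derive a stage-specific sub-seed from a global seed
#'
#' One global seed governs a pipeline run; each stochastic stage derives its
#' own seed deterministically from the stage name, so adding a stage never
#' shifts another stage's random stream.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in [0, 2^31).
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003L
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(name, " must be a finite number in [", lo, ", ", hi, "]")
  invisible(x)
}
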