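# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-stream seed: polynomial string hash folded into the
# base seed, kept below 2^31 so it is a valid R integer seed.
#' @noRd
substream_seed <- function(seed, tag) {
  h <- 0
  for (k in utf8ToInt(as.character(tag))) h <- (h * 31 + k) %% 2147483647L
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Runs of TRUE in a logical vector: data.frame(start, end, length).
#' @noRd
true_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(as.vector(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# md5 of the canonical JSON serialisation of a list (for run manifests).
#' @noRd
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' @noRd
roi_levels <- function() {
  c("Visual", "ATL", "TPJ", "PMC", "amPFC", "dmPFC", "vmPFC", "none")
}

#' @noRd
condition_levels <- function() {
  c("self", "other", "cognitive", "episodic", "semantic", "rest")
}
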