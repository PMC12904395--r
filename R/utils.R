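#' Deterministic child seed derivation
#'
#' One top-level seed fans out into per-stage / per-image child seeds by a
#' fixed rule: the parent seed and each tag (stage name, image index, ...)
#' are folded into a 31-bit integer with the multiplicative hash
#' `h <- (h * 1000003 + x) mod (2^31 - 1)`, character tags entering via
#' their byte values. The result is always a valid 32-bit R seed.
#'
#' @param seed parent integer seed.
#' @param ... tags (integers or strings) identifying the child stream.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (tag in list(...)) {
    xs <- if (is.character(tag)) as.integer(charToRaw(paste(tag, collapse = "|"))) else as.integer(tag)
    for (x in xs) h <- (h * 1000003 + (as.numeric(x) %% m)) %% m
  }
  as.integer(h %% (m - 2)) + 1L
}

# natural-order key: "img10" sorts after "img2"
natural_order <- function(x) {
  x <- as.character(x)
  pieces <- strsplit(gsub("([0-9]+)", "\001\\1\001", x), "\001")
  width <- 20L
  key <- vapply(pieces, function(p) {
    num <- grepl("^[0-9]+$", p)
    p[num] <- formatC(as.numeric(p[num]), width = width, format = "f",
                      digits = 0, flag = "0")
    paste(p, collapse = "")
  }, character(1))
  order(key, x)
}

# median over finite values; NA when none survive; records exclusions
median_finite <- function(x) {
  keep <- is.finite(x)
  if (!any(keep)) return(structure(NA_real_, n_excluded = sum(!keep)))
  structure(stats::median(x[keep]), n_excluded = sum(!keep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# logistic helpers for features bounded in (0, 1)
logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
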