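# Internal helpers shared across modules.

#' Signal a classed pksminer error
#' @noRd
pks_abort <- function(message, class) {
  stop(structure(
    class = c(class, "pks_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Run code with a temporarily fixed RNG state
#'
#' Restores (or removes) the caller's `.Random.seed` afterwards so fixture
#' generation is deterministic without disturbing the session RNG.
#' @noRd
with_rng_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Lower-case alphanumeric tokens of a free-text product string
#' @noRd
text_tokens <- function(x) {
  x <- tolower(x)
  tokens <- strsplit(gsub("[^a-z0-9]+", " ", x), " +")[[1]]
  tokens[nzchar(tokens)]
}

#' Does EC string `a` match EC string `b`, honouring "-" wildcards?
#'
#' Both sides may carry wildcards (e.g. catalogue "2.1.1.-" matches an
#' annotated "2.1.1.77").
#' @noRd
ec_matches <- function(a, b) {
  fa <- strsplit(a, ".", fixed = TRUE)[[1]]
  fb <- strsplit(b, ".", fixed = TRUE)[[1]]
  if (length(fa) != 4L || length(fb) != 4L) return(FALSE)
  all(fa == fb | fa == "-" | fb == "-")
}

#' Validate an EC-number string (d.d.d.d with "-" wildcards)
#' @noRd
is_valid_ec <- function(x) {
  grepl("^([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$", x)
}

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Check an amino-acid string (20 letters plus X)
#' @noRd
is_valid_protein <- function(x) {
  !grepl("[^ACDEFGHIKLMNPQRSTVWYX]", toupper(x))
}

#' Wrap a long string into fixed-width lines
#' @noRd
wrap_fixed <- function(x, width) {
  if (nchar(x) <= width) return(x)
  starts <- seq(1L, nchar(x), by = width)
  substring(x, starts, pmin(starts + width - 1L, nchar(x)))
}

#' Greedy word-boundary wrap (words longer than `width` stand alone)
#' @noRd
wrap_words <- function(x, width) {
  words <- strsplit(x, " ", fixed = TRUE)[[1]]
  lines <- character(); cur <- ""
  for (w in words) {
    cand <- if (nzchar(cur)) paste(cur, w) else w
    if (nchar(cand) > width && nzchar(cur)) {
      lines <- c(lines, cur); cur <- w
    } else cur <- cand
  }
  c(lines, cur)
}

#' Stable checksum of an R object (via serialization to a temp file)
#' @noRd
object_checksum <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
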