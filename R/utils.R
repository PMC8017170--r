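#' @keywords internal
#' @useDynLib ecgfb, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Default class vocabulary
#'
#' The nine cardiac states of the default vocabulary: atrial fibrillation
#' (AF), first-degree atrioventricular block (I-AVB), left/right bundle
#' branch block (LBBB/RBBB), normal sinus rhythm (Normal), premature
#' atrial/ventricular contraction (PAC/PVC), and ST-segment
#' depression/elevation (STD/STE).
#'
#' @return Character vector of the nine class names.
#' @export
ecg_classes <- function() {
  c("AF", "I-AVB", "LBBB", "Normal", "PAC", "PVC", "RBBB", "STD", "STE")
}

#' Standard 12-lead names
#' @return Character vector of the 12 standard lead names.
#' @export
ecg_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

# Condition constructors: every package error carries a subclass so callers
# (and tests) can discriminate failure modes without string matching.
stop_ecgfb <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "ecgfb_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a named substream seed from a root seed. All pipeline randomness
# flows from one root seed through these; the map is a fixed integer hash
# kept below 2^31.
seed_stream <- function(root, name) {
  h <- as.double(root %% 2147483647L)
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483629
  as.integer(h %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
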