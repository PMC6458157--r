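# Shared internal helpers.

# Comma is the default dialect; a tab dialect is auto-detected from the header
# line, as both are common instrument exports.
detectSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("file is empty: ", path)
  nTab <- lengths(regmatches(header, gregexpr("\t", header)))
  nComma <- lengths(regmatches(header, gregexpr(",", header)))
  if (nTab > nComma) "\t" else ","
}

readDelimAuto <- function(path) {
  utils::read.table(path, header = TRUE, sep = detectSep(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = character(0), quote = "\"",
                    comment.char = "")
}

# standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))

# Deterministic sub-seed derivation: all randomness in the simulator flows
# from one master seed; each sub-stream gets seed + a fixed small offset,
# kept below 2^31.
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

# Evaluate expr under a temporary RNG state so callers' streams are
# untouched.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

isCaseVector <- function(labels, caseClass = NULL) {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  u <- unique(labels)
  if (length(u) < 2L)
    stop("both classes must be present")
  if (is.null(caseClass)) {
    if (length(u) != 2L)
      stop("labels have ", length(u), " classes; supply 'caseClass'")
    caseClass <- sort(u)[2L]
  }
  labels == caseClass
}
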