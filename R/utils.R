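## Internal utilities shared across modules.

#' @importFrom methods new is validObject slot setValidity show
#' @importFrom stats setNames rpois runif rgeom
#' @importFrom utils read.table write.table head tail
#' @importClassesFrom Biostrings DNAString
#' @importMethodsFrom Biostrings show
NULL

## Classed conditions so callers can distinguish failure modes.
hpStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "hp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

hpWarn <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  warning(structure(
    class = c(class, "hp_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate expr with a temporarily seeded RNG, restoring the caller's
## RNG state afterwards so package functions never clobber user seeds.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(saved)) {
      assign(".Random.seed", saved, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## Upper-case nucleotide normalization: U -> T, keep IUPAC codes and gaps.
normalizeResidues <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

IUPAC_NT <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

isUnambiguousBase <- function(ch) ch %in% c("A", "C", "G", "T")
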