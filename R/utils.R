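#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# canonical chrom-pos-ref-alt join key used across all tables
#' Canonical variant key
#'
#' Builds the `chrom-pos-ref-alt` string used as the join key between call
#' tables, annotation tables and truth tables (e.g. `"12-2613692-G-A"`).
#'
#' @param chrom Chromosome label.
#' @param pos 1-based position.
#' @param ref,alt Reference and alternate allele strings.
#' @return Character vector of variant keys.
#' @export
#' @examples
#' variant_key("12", 2613692, "G", "A")
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = "-")
}

# evaluate `code` under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# simple per-session cache (toy genome, calibrated rate tables)
.tb_cache <- new.env(parent = emptyenv())

cache_get_or <- function(key, compute) {
  if (!is.null(.tb_cache[[key]])) return(.tb_cache[[key]])
  val <- compute()
  .tb_cache[[key]] <- val
  val
}

stop_tb <- function(...) stop(..., call. = FALSE)

round1 <- function(x) round(x, 1)
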