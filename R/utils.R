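#' @keywords internal
"_PACKAGE"

# sprintf-style stop/warning without call noise
stopf <- function(fmt, ..., class = "sdegtools_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# TSV writers/readers used across modules; all pipeline tables are plain
# tab-separated text with a header row and no quoting.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

SEXES  <- c("female", "male", "supermale")
ORGANS <- c("tepal", "pistil", "stamen", "bud", "speartip")
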