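#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm p.adjust phyper rnorm runif qnorm setNames
#'   ks.test var ave
#' @importFrom utils read.delim write.table head
NULL

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a deterministic sub-seed from a master seed and a label
#'
#' Each stochastic component of the toolkit draws its own seed from the
#' single master seed by hashing (label, master), so adding a new component
#' never perturbs the random streams of existing ones.
#'
#' @param label character scalar naming the component.
#' @param master integer master seed.
#' @return An integer in \[0, 2^31).
#' @export
derive_seed <- function(label, master) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(master), length(master) == 1L)
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Tab-separated UTF-8 with one header line; missing values are literal "NA".
.read_tsv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = "NA", quote = "",
             comment.char = "")
}

.write_tsv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    .stopf("%s: missing column(s) %s", what, paste(missing, collapse = ", "))
  invisible(df)
}
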