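#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Holm–Šidák step-down multiple-testing correction
#'
#' Adjusted p-values are \eqn{1 - (1 - p_{(i)})^{m - i + 1}} over the sorted
#' p-values, made monotone by a running maximum (step-down).
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return numeric vector of adjusted p-values, same order as `p`.
#' @export
holm_sidak <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  m <- sum(!is.na(p))
  if (m == 0L) return(p)
  ord <- order(p, na.last = TRUE)
  adj <- rep(NA_real_, length(p))
  ranked <- p[ord][seq_len(m)]
  a <- 1 - (1 - ranked)^(m - seq_len(m) + 1)
  adj[ord[seq_len(m)]] <- pmin(1, cummax(a))
  adj
}

# Derive a child RNG seed from a root seed and a stream index; kept below
# 2^31 so it is always a valid R integer.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483647)
}

# TSV conventions: tab-delimited, header mandatory, '.' for missing.
read_tsv_strict <- function(path, col_types = NULL) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = ".",
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (!is.null(col_types)) {
    for (nm in names(col_types)) {
      if (!nm %in% names(df)) {
        stop("file ", basename(path), " lacks required column '", nm, "'",
             call. = FALSE)
      }
      if (col_types[[nm]] == "numeric") {
        val <- suppressWarnings(as.numeric(df[[nm]]))
        bad <- which(!is.na(df[[nm]]) & is.na(val))
        if (length(bad)) {
          stop("malformed numeric in ", basename(path), " column '", nm,
               "' at line ", bad[1] + 1L, call. = FALSE)
        }
        df[[nm]] <- val
      } else if (col_types[[nm]] == "integer") {
        val <- suppressWarnings(as.integer(df[[nm]]))
        bad <- which(!is.na(df[[nm]]) & is.na(val))
        if (length(bad)) {
          stop("malformed integer in ", basename(path), " column '", nm,
               "' at line ", bad[1] + 1L, call. = FALSE)
        }
        df[[nm]] <- val
      }
    }
  }
  df
}

write_tsv_strict <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    v <- df2[[j]]
    if (is.numeric(v)) v <- sprintf("%.15g", v)
    v[is.na(df[[j]])] <- "."
    df2[[j]] <- v
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# cosine distance between two non-negative activity vectors
cosine_distance <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  1 - sum(x * y) / (nx * ny)
}
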