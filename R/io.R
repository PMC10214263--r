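# Tabular readers/writers.  CSV/TSV are the only interchange formats:
# pathology and clinical tables are inherently tabular and diff-able.

#' Read a genes x samples expression table
#'
#' Expects a TSV (or CSV) whose first column is the gene id and whose
#' header row holds sample ids.  Duplicate gene ids are resolved by
#' keeping the maximum-variance row (logged); duplicate sample ids,
#' non-numeric cells, and missing values are errors naming the
#' location.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]][-1]
  if (anyDuplicated(header))
    stop("parse error: duplicate sample id(s): ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character")
  genes <- raw[[1]]
  body <- raw[, -1, drop = FALSE]
  colnames(body) <- header
  m <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(genes, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      cell <- body[[j]][bad[1]]
      stop("parse error: non-numeric or missing value at gene '",
           genes[bad[1]], "', sample '", colnames(body)[j], "' (value: '",
           cell, "')")
    }
    m[, j] <- v
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("duplicate gene id(s) resolved by max variance: ",
            paste(dup, collapse = ", "))
    keep <- unlist(lapply(split(seq_len(nrow(m)), genes), function(idx) {
      if (length(idx) == 1) return(idx)
      idx[which.max(apply(m[idx, , drop = FALSE], 1, stats::var))]
    }))
    m <- m[sort(keep), , drop = FALSE]
  }
  m
}

#' Write a genes x samples expression table
#'
#' @param expression numeric matrix with gene rownames.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_expression <- function(expression, path, sep = "\t") {
  df <- data.frame(gene = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-cohort z-scoring of expression
#'
#' Within each cohort, every gene is centered and scaled to unit SD; a
#' simple cross-cohort harmonization stand-in.  Zero-SD genes are set
#' to 0 and flagged via the `constant_genes` attribute.
#'
#' @param cohorts named list of genes x samples matrices (or of lists
#'   with an `expression` element).
#' @return list of standardized matrices (same shape), each carrying a
#'   `constant_genes` attribute.
#' @export
zscore_by_cohort <- function(cohorts) {
  lapply(cohorts, function(co) {
    m <- if (is.list(co)) co$expression else co
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    const <- sdv == 0
    z <- (m - mu) / ifelse(const, 1, sdv)
    z[const, ] <- 0
    attr(z, "constant_genes") <- rownames(m)[const]
    z
  })
}
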