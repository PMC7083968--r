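#' Read and validate a screen table from CSV
#'
#' The long-format screen schema is `drugA, drugB, cell_line, concA_uM,
#' concB_uM, viability, replicate`; single-agent rows have an empty/NA
#' `drugB` and `concB_uM = 0`.  Concentrations are micromolar, viability
#' fractional (1 = untreated).  Malformed rows are reported with their
#' row numbers.
#'
#' @param path CSV file path.
#' @return validated `data.frame` of class `screen_table`.
#' @export
read_screen_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drugA", "drugB", "cell_line", "concA_uM", "concB_uM",
            "viability", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  df$drugB[!is.na(df$drugB) & df$drugB == ""] <- NA_character_
  bad <- which(!is.finite(df$concA_uM) | df$concA_uM < 0 |
               !is.finite(df$concB_uM) | df$concB_uM < 0)
  if (length(bad))
    stop("negative or non-numeric concentrations in rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  # unclipped measurement noise legitimately produces viabilities slightly
  # below 0 or above 1; only reject gross corruption
  bad <- which(!is.finite(df$viability) | df$viability < -0.5 |
               df$viability > 2)
  if (length(bad))
    stop("implausible or non-numeric viability in rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(is.na(df$drugB) & df$concB_uM != 0)
  if (length(bad))
    stop("single-agent rows must have concB_uM = 0; offending rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  combos <- df[!is.na(df$drugB), ]
  singles <- unique(df$drugA[is.na(df$drugB)])
  orphan <- setdiff(unique(c(combos$drugA, combos$drugB)), singles)
  if (length(orphan))
    warning("combination drugs without single-agent records: ",
            paste(orphan, collapse = ", "))
  class(df) <- c("screen_table", "data.frame")
  df
}

#' @rdname read_screen_csv
#' @param screen a screen table (or `synthetic_screen`).
#' @export
write_screen_csv <- function(screen, path) {
  if (inherits(screen, "synthetic_screen")) screen <- screen$screen
  utils::write.csv(screen, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a gene x cell-line expression matrix from CSV
#'
#' First column holds gene identifiers; remaining columns are cell lines.
#'
#' @param path CSV file path.
#' @return numeric matrix with gene rownames and cell-line colnames.
#' @export
read_expression_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("expression values must be numeric")
  rownames(m) <- genes
  m
}

#' @rdname read_expression_csv
#' @param expr genes x cell-lines matrix.
#' @export
write_expression_csv <- function(expr, path) {
  utils::write.csv(data.frame(gene = rownames(expr), expr,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a dendrogram's merge history as nested text
#'
#' Serialises a [cluster_by_similarity()] result as a Newick-like nested
#' grouping with merge similarities as branch annotations.
#'
#' @param dendro a `similarity_dendrogram`.
#' @param path optional file; when `NULL` the string is returned.
#' @return the nested text (invisibly when written to file).
#' @export
write_dendrogram_text <- function(dendro, path = NULL) {
  n <- length(dendro$labels)
  nodes <- as.list(dendro$labels)
  sets <- as.list(dendro$labels)
  for (step in seq_len(nrow(dendro$merges))) {
    members <- strsplit(dendro$merges$members[step], ",")[[1]]
    hit <- which(vapply(sets, function(s) all(s %in% members) &&
                          length(intersect(s, members)) > 0, logical(1)))
    merged_txt <- paste0("(", paste(unlist(nodes[hit]), collapse = ","),
                         "):", signif(dendro$merges$similarity[step], 4))
    keep <- setdiff(seq_along(sets), hit)
    sets <- c(sets[keep], list(members))
    nodes <- c(nodes[keep], list(merged_txt))
  }
  txt <- paste0(nodes[[1]], ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
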