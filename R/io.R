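# Readers and writers: expression TSV, edge-list TSV / SIF, GMT.

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  genes <- as.character(df[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
      stop("non-numeric value at row ", bad, ", column ",
           colnames(vals)[j], " of ", path)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  m
}

#' Write an expression matrix to TSV
#'
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path file path.
#' @export
write_expression <- function(expr, path) {
  check_expr(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: name, description, then tab-separated genes.
#' Duplicate genes within a line are removed.
#'
#' @param path file path.
#' @return named list of character vectors, with set descriptions
#'   stored in the attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, " in ", path, ": fewer than 3 fields")
    sets[[f[1L]]] <- unique(f[-(1:2)])
    desc[f[1L]] <- f[2L]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional character vector of set descriptions
#'   (recycled; defaults to the set name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a network from an edge-list TSV or SIF file
#'
#' TSV: header `gene_a<TAB>gene_b[<TAB>weight]`.  SIF: `a relation b`
#' per line (whitespace separated), relation token ignored.  Edges are
#' deduplicated as undirected pairs; self-loops are dropped with a
#' message.
#'
#' @param path file path.
#' @param format `"tsv"` or `"sif"`.
#' @param genes optional gene universe; defaults to the genes seen in
#'   the file.
#' @return undirected igraph.
#' @export
read_network <- function(path, format = c("tsv", "sif"), genes = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
    if (ncol(df) < 2L) stop("edge-list TSV needs at least 2 columns: ", path)
    a <- as.character(df[[1L]]); b <- as.character(df[[2L]])
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    f <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(vapply(f, length, 0L) == 2L)
    if (length(bad))
      stop("malformed SIF line ", bad[1L], " in ", path)
    f <- f[vapply(f, length, 0L) >= 3L]
    a <- vapply(f, `[`, "", 1L); b <- vapply(f, `[`, "", 3L)
  }
  loops <- sum(a == b)
  if (loops > 0L) message("dropped ", loops, " self-loop(s) from ", path)
  if (is.null(genes)) genes <- sort(unique(c(a, b)))
  graph_from_edges(data.frame(from = a, to = b, stringsAsFactors = FALSE),
                   genes)
}

#' Write a network to an edge-list TSV or SIF file
#'
#' @param net undirected igraph.
#' @param path file path.
#' @param format `"tsv"` (columns gene_a, gene_b, weight) or `"sif"`
#'   (constant relation token `pp`).
#' @export
write_network <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  e <- igraph::ends(net, igraph::E(net), names = TRUE)
  if (format == "tsv") {
    w <- if ("weight" %in% igraph::edge_attr_names(net))
      igraph::E(net)$weight else rep(1, nrow(e))
    df <- data.frame(gene_a = e[, 1L], gene_b = e[, 2L], weight = w)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(if (nrow(e)) paste(e[, 1L], "pp", e[, 2L]) else character(0),
               path)
  }
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' Two-column TSV (probe_id, gene_id) with a header.
#'
#' @param path file path.
#' @return named character vector mapping probe ids to gene ids.
#' @export
read_probe_mapping <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) stop("probe mapping needs 2 columns: ", path)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
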