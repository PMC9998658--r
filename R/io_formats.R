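#' @title Readers and writers for the pipeline's external formats
#' @description Strict TSV dialects (UTF-8, header row, decimal point) so
#'   synthetic fixtures and real exports are interchangeable. Loaders never
#'   silently drop rows: every exclusion is counted in a load report attached
#'   to the returned object as the `"load_report"` attribute.
#' @name io_formats
NULL

read_tsv_strict <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "",
                    fileEncoding = "UTF-8")
}

write_tsv_strict <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
}

#' Read a MaxQuant-style protein-groups table
#'
#' Expects one `LFQ intensity <run_id>` column per run listed in the
#' metadata, and the flag columns `Only identified by site`,
#' `Potential contaminant` and `Reverse` holding `"+"` or empty. Cells that
#' are absent, empty or zero load as the value 0; the missing-vs-zero
#' distinction is introduced later by [drop_zero_observations()].
#'
#' @param path protein-groups TSV.
#' @param metadata_path run-metadata TSV (see [read_run_metadata()]).
#' @return an [lfq_dataset()] on the raw scale (`log2_scale = FALSE`), with a
#'   `"load_report"` attribute counting rows read and excluded.
#' @export
read_protein_groups <- function(path, metadata_path) {
  runs <- read_run_metadata(metadata_path)
  tab <- read_tsv_strict(path)
  id_col <- intersect(c("Protein IDs", "protein_id"), names(tab))[1]
  if (is.na(id_col)) stop("protein-groups table needs a 'Protein IDs' or 'protein_id' column")
  gene_col <- intersect(c("Gene names", "gene_name"), names(tab))[1]

  lfq_cols <- paste("LFQ intensity", runs$run_id)
  miss <- lfq_cols[!lfq_cols %in% names(tab)]
  if (length(miss))
    stop("no LFQ intensity column for run(s): ",
         paste(sub("^LFQ intensity ", "", miss), collapse = ", "))

  flag <- function(col) {
    if (!col %in% names(tab)) return(rep(FALSE, nrow(tab)))
    v <- trimws(as.character(tab[[col]]))
    !is.na(v) & v == "+"
  }
  proteins <- data.frame(
    protein_id = as.character(tab[[id_col]]),
    gene_name = if (!is.na(gene_col)) as.character(tab[[gene_col]]) else as.character(tab[[id_col]]),
    flag_site_only = flag("Only identified by site"),
    flag_contaminant = flag("Potential contaminant"),
    flag_reverse = flag("Reverse"),
    stringsAsFactors = FALSE
  )
  if (any(proteins$protein_id == "")) stop("empty protein_id")
  if (anyDuplicated(proteins$protein_id))
    stop("duplicate protein_id: ",
         proteins$protein_id[duplicated(proteins$protein_id)][1])

  m <- sapply(lfq_cols, function(cl) {
    v <- suppressWarnings(as.numeric(tab[[cl]]))
    v[is.na(v)] <- 0
    v
  })
  m <- matrix(m, nrow = nrow(tab), dimnames = list(proteins$protein_id, runs$run_id))
  if (any(m < 0)) stop("negative LFQ intensity encountered")
  ds <- lfq_dataset(m, runs, proteins, log2_scale = FALSE)
  attr(ds, "load_report") <- data.frame(
    what = c("proteins_read", "runs_read"),
    n = c(nrow(proteins), nrow(runs)))
  ds
}

#' Write an LFQ dataset as a protein-groups TSV + metadata TSV
#'
#' Inverse of [read_protein_groups()]: missing cells are written as 0 (the
#' MaxQuant non-observation convention), so round-tripping is exact for raw
#' datasets whose zeros have not yet been converted to missing.
#'
#' @param ds an `lfq_dataset` on the raw scale.
#' @param path,metadata_path output TSV paths.
#' @export
write_protein_groups <- function(ds, path, metadata_path) {
  if (ds$log2_scale) stop("write_protein_groups expects the raw scale")
  m <- ds$intensity
  m[is.na(m)] <- 0
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    `Protein IDs` = ds$proteins$protein_id,
    `Gene names` = ds$proteins$gene_name,
    `Only identified by site` = ifelse(ds$proteins$flag_site_only, "+", ""),
    `Potential contaminant` = ifelse(ds$proteins$flag_contaminant, "+", ""),
    `Reverse` = ifelse(ds$proteins$flag_reverse, "+", ""))
  # %.17g preserves doubles exactly across the round trip
  im <- as.data.frame(apply(m, 2, function(v) sprintf("%.17g", v)),
                      check.names = FALSE)
  names(im) <- paste("LFQ intensity", colnames(m))
  write_tsv_strict(cbind(out, im), path)
  write_run_metadata(ds$runs, metadata_path)
  invisible(path)
}

#' Read/write the sample-metadata table
#'
#' Columns: `run_id`, `genetic_context`, `culture_context`, `concentration`,
#' `bio_rep`, `tech_rep`, `is_control`. Control rows carry the sentinel
#' `"ctrl"` in the context columns.
#'
#' @param path metadata TSV.
#' @return data.frame of run metadata.
#' @export
read_run_metadata <- function(path) {
  runs <- read_tsv_strict(path)
  runs$run_id <- as.character(runs$run_id)
  runs$concentration <- as.character(runs$concentration)
  runs$is_control <- as.logical(runs$is_control)
  runs$bio_rep <- as.integer(runs$bio_rep)
  runs$tech_rep <- as.integer(runs$tech_rep)
  validate_run_meta(runs)
}

#' @rdname read_run_metadata
#' @param runs run-metadata data.frame.
#' @export
write_run_metadata <- function(runs, path) {
  write_tsv_strict(runs, path)
  invisible(path)
}

#' Read a STRING-style weighted edge list
#'
#' @param path TSV with columns `node_a`, `node_b`, `score`.
#' @param score_scale `"0-1"` or `"0-1000"`; a 0-1000 input is divided by
#'   1000 so scores are always returned on \[0,1\].
#' @return data.frame (`node_a`, `node_b`, `score`) of undirected unique
#'   edges with `node_a < node_b` lexicographically; self-loops dropped and
#'   duplicate edges collapsed to the maximum score (conservative against
#'   losing high-confidence evidence). A `"load_report"` attribute counts
#'   the dropped/merged rows.
#' @export
read_edge_list <- function(path, score_scale = c("0-1", "0-1000")) {
  score_scale <- match.arg(score_scale)
  tab <- read_tsv_strict(path)
  need <- c("node_a", "node_b", "score")
  if (!all(need %in% names(tab)))
    stop("edge list needs columns: ", paste(need, collapse = ", "))
  sc <- as.numeric(tab$score)
  hi <- if (score_scale == "0-1") 1 else 1000
  if (any(is.na(sc)) || any(sc < 0 | sc > hi))
    stop("score outside declared scale ", score_scale)
  if (score_scale == "0-1000") sc <- sc / 1000
  a <- as.character(tab$node_a); b <- as.character(tab$node_b)
  self <- a == b
  a <- a[!self]; b <- b[!self]; sc <- sc[!self]
  lo <- pmin(a, b); hi2 <- pmax(a, b)
  key <- paste(lo, hi2, sep = "\r")
  agg <- tapply(sc, key, max)
  first <- !duplicated(key)
  edges <- data.frame(node_a = lo[first], node_b = hi2[first],
                      score = as.numeric(agg[key[first]]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "load_report") <- data.frame(
    what = c("rows_read", "self_loops_dropped", "duplicates_merged"),
    n = c(nrow(tab), sum(self), length(key) - nrow(edges)))
  edges
}

#' @rdname read_edge_list
#' @param edges edge data.frame as returned by `read_edge_list`.
#' @export
write_edge_list <- function(edges, path) {
  write_tsv_strict(edges[c("node_a", "node_b", "score")], path)
  invisible(path)
}

#' Read a Gene Ontology subset in OBO format
#'
#' Parses the fields the pipeline needs: `id`, `name`, `namespace`, `is_a`
#' and `relationship: part_of`. Acyclicity of the combined edge set is
#' verified on load.
#'
#' @param path OBO file.
#' @return a `go_dag`: list with `terms` (data.frame `id`, `name`,
#'   `namespace`) and `edges` (data.frame `child`, `parent`, `type` in
#'   `is_a`/`part_of`).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  terms <- list(); edges <- list()
  cur <- NULL; in_term <- FALSE
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id)) return(NULL)
    cur
  }
  for (ln in c(lines, "[flush]")) {
    ln <- trimws(ln)
    if (startsWith(ln, "[")) {
      if (in_term && !is.null(cur$id)) {
        terms[[length(terms) + 1L]] <- cur[c("id", "name", "namespace")]
        for (p in cur$is_a) edges[[length(edges) + 1L]] <- list(cur$id, p, "is_a")
        for (p in cur$part_of) edges[[length(edges) + 1L]] <- list(cur$id, p, "part_of")
      }
      in_term <- identical(ln, "[Term]")
      cur <- list(id = NULL, name = NA_character_, namespace = NA_character_,
                  is_a = character(), part_of = character())
      next
    }
    if (!in_term || ln == "") next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "namespace:")) cur$namespace <- trimws(sub("^namespace:", "", ln))
    else if (startsWith(ln, "is_a:"))
      cur$is_a <- c(cur$is_a, trimws(sub("!.*$", "", sub("^is_a:", "", ln))))
    else if (startsWith(ln, "relationship: part_of"))
      cur$part_of <- c(cur$part_of, trimws(sub("!.*$", "", sub("^relationship: part_of", "", ln))))
  }
  if (!length(terms)) stop("no [Term] stanzas found in ", path)
  terms <- data.frame(id = vapply(terms, `[[`, "", "id"),
                      name = vapply(terms, `[[`, "", "name"),
                      namespace = vapply(terms, `[[`, "", "namespace"),
                      stringsAsFactors = FALSE)
  if (length(edges)) {
    edges <- data.frame(child = vapply(edges, `[[`, "", 1),
                        parent = vapply(edges, `[[`, "", 2),
                        type = vapply(edges, `[[`, "", 3),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(child = character(), parent = character(),
                        type = character(), stringsAsFactors = FALSE)
  }
  go_dag(terms, edges)
}

#' Construct and validate a GO DAG
#'
#' @param terms data.frame `id`, `name`, `namespace`.
#' @param edges data.frame `child`, `parent`, `type`.
#' @return a validated `go_dag` object.
#' @export
go_dag <- function(terms, edges) {
  if (anyDuplicated(terms$id)) stop("duplicate term id")
  unknown <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(unknown)) stop("edge references unknown term: ", unknown[1])
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[c("child", "parent")],
                                       vertices = terms$id, directed = TRUE)
    if (!igraph::is_dag(g)) stop("cycle in is_a/part_of closure")
  }
  structure(list(terms = terms, edges = edges), class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms, %d edges (%d is_a, %d part_of)\n",
              nrow(x$terms), nrow(x$edges), sum(x$edges$type == "is_a"),
              sum(x$edges$type == "part_of")))
  invisible(x)
}

#' Write a GO DAG in OBO subset format
#'
#' @param dag a `go_dag`.
#' @param path output file.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag$terms))) {
    t <- dag$terms[i, ]
    writeLines(c("", "[Term]", paste0("id: ", t$id), paste0("name: ", t$name),
                 paste0("namespace: ", t$namespace)), con)
    e <- dag$edges[dag$edges$child == t$id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      if (e$type[j] == "is_a") writeLines(paste0("is_a: ", e$parent[j]), con)
      else writeLines(paste0("relationship: part_of ", e$parent[j]), con)
    }
  }
  invisible(path)
}

#' Read/write gene-to-term annotations (GAF-like two-column TSV)
#'
#' Rows annotating a term absent from `dag` are skipped with a warning and
#' counted in the load report.
#'
#' @param path TSV with columns `gene`, `term`.
#' @param dag optional `go_dag` used to validate term ids.
#' @return data.frame (`gene`, `term`), unique rows, with a `"load_report"`
#'   attribute.
#' @export
read_gaf <- function(path, dag = NULL) {
  tab <- read_tsv_strict(path)
  if (!all(c("gene", "term") %in% names(tab)))
    stop("annotation table needs columns gene, term")
  ann <- unique(data.frame(gene = as.character(tab$gene),
                           term = as.character(tab$term),
                           stringsAsFactors = FALSE))
  skipped <- 0L
  if (!is.null(dag)) {
    ok <- ann$term %in% dag$terms$id
    skipped <- sum(!ok)
    if (skipped) {
      warning(skipped, " annotation row(s) reference unknown terms; skipped")
      ann <- ann[ok, , drop = FALSE]
    }
  }
  rownames(ann) <- NULL
  attr(ann, "load_report") <- data.frame(
    what = c("rows_read", "unknown_term_skipped"),
    n = c(nrow(tab), skipped))
  ann
}

#' @rdname read_gaf
#' @param ann annotation data.frame (`gene`, `term`).
#' @export
write_gaf <- function(ann, path) {
  write_tsv_strict(ann[c("gene", "term")], path)
  invisible(path)
}
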