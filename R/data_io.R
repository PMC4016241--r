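# Readers and writers for every external format the pipeline touches.
# All tabular formats are tab-separated UTF-8; lines starting with '#' are
# comments. Readers validate strictly so downstream code only sees clean
# in-memory objects.

read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a gene-gene edge list
#'
#' Parses a 2- or 3-column TSV (`gene_a`, `gene_b`, optional `weight`; weight
#' defaults to 1). Edges are undirected: duplicate pairs are collapsed keeping
#' the maximum weight, and self-loops are dropped (their count is kept in the
#' `n_self_loops` attribute).
#'
#' @param path path to a TSV file.
#' @return a tibble with columns `from`, `to`, `weight` (one row per
#'   undirected edge, `from < to` lexicographically), class `edge_set`;
#'   attributes `n_self_loops` and `n_duplicates`.
#' @export
read_edge_list <- function(path) {
  parsed <- read_tsv_lines(path)
  if (length(parsed$lines) == 0) {
    ed <- tibble::tibble(from = character(), to = character(), weight = double())
    return(structure(ed, class = c("edge_set", class(ed)),
                     n_self_loops = 0L, n_duplicates = 0L))
  }
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed edge line %d: expected 2 or 3 tab-separated fields",
                  parsed$lineno[bad[1]]))
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  w <- vapply(seq_along(fields), function(i) {
    if (nf[i] == 3L) {
      wi <- suppressWarnings(as.numeric(fields[[i]][3L]))
      if (is.na(wi)) abort(sprintf("malformed edge line %d: non-numeric weight",
                                   parsed$lineno[i]))
      wi
    } else 1.0
  }, 0.0)
  if (any(w < 0)) {
    abort(sprintf("negative edge weight on line %d",
                  parsed$lineno[which(w < 0)[1]]))
  }
  stopifnot_gene_ids(c(a, b))
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]; w <- w[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  n_dup <- sum(duplicated(key))
  if (n_dup > 0) {
    w <- tapply(w, key, max)
    uk <- names(w)
    parts <- strsplit(uk, "\r", fixed = TRUE)
    lo <- vapply(parts, `[[`, "", 1L)
    hi <- vapply(parts, `[[`, "", 2L)
    w <- as.numeric(w)
  }
  ord <- order(lo, hi, method = "radix")
  ed <- tibble::tibble(from = lo[ord], to = hi[ord], weight = w[ord])
  structure(ed, class = c("edge_set", class(ed)),
            n_self_loops = as.integer(n_self), n_duplicates = as.integer(n_dup))
}

#' Write a gene-gene edge list
#' @param edges an `edge_set` tibble (or any data frame with columns
#'   `from`, `to`, `weight`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  writeLines(sprintf("%s\t%s\t%s", edges$from, edges$to,
                     sprintf("%.17g", edges$weight)),
             path)
  invisible(path)
}

#' Read a gene-by-tissue expression matrix
#'
#' TSV with a header row of tissue names and gene ids in the first column.
#' Rows containing any non-numeric or missing cell are dropped; the count of
#' dropped rows is kept in the `n_dropped` attribute.
#'
#' @param path path to a TSV file.
#' @return an `expression_table`: list with `genes`, `tissues`, and a
#'   genes-by-tissues numeric matrix `values`.
#' @export
read_expression <- function(path) {
  parsed <- read_tsv_lines(path)
  if (length(parsed$lines) < 2) abort("expression file is empty or has no data rows")
  header <- strsplit(parsed$lines[1], "\t", fixed = TRUE)[[1]]
  tissues <- header[-1]
  if (length(tissues) == 0) abort("expression file has no tissue columns")
  body <- strsplit(parsed$lines[-1], "\t", fixed = TRUE)
  nf <- lengths(body)
  bad <- which(nf != length(header))
  if (length(bad) > 0) {
    abort(sprintf("malformed expression line %d: expected %d fields, got %d",
                  parsed$lineno[-1][bad[1]], length(header), nf[bad[1]]))
  }
  genes <- vapply(body, `[[`, "", 1L)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene row(s) in expression table: %s",
                  paste(utils::head(dup, 5), collapse = ", ")))
  }
  stopifnot_gene_ids(genes)
  vals <- suppressWarnings(
    do.call(rbind, lapply(body, function(f) as.numeric(f[-1])))
  )
  ok <- rowSums(is.na(vals)) == 0
  n_dropped <- sum(!ok)
  new_expression_table(genes[ok], tissues, vals[ok, , drop = FALSE],
                       n_dropped = n_dropped)
}

new_expression_table <- function(genes, tissues, values, n_dropped = 0L) {
  rownames(values) <- genes
  colnames(values) <- tissues
  structure(list(genes = genes, tissues = tissues, values = values),
            class = "expression_table", n_dropped = as.integer(n_dropped))
}

#' @exportS3Method base::print
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d genes x %d tissues (%d rows dropped on load)\n",
              length(x$genes), length(x$tissues), attr(x, "n_dropped") %||% 0L))
  invisible(x)
}

#' Write an expression table
#' @param expr an `expression_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", expr$tissues), collapse = "\t"), con)
  body <- apply(expr$values, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(expr$genes, body, sep = "\t"), con)
  invisible(path)
}

#' Read an OBO 1.2 ontology
#'
#' Minimal stanza parser: only `[Term]` stanzas and the `id`, `namespace`,
#' `is_a`, `relationship: part_of` and `is_obsolete` fields are consulted.
#' Obsolete terms are excluded. Terms are grouped per namespace into DAGs with
#' typed parent edges; a cycle raises an error naming one member.
#'
#' @param path path to an OBO file.
#' @return an `ontology_set`: named list of per-namespace DAGs, each a list
#'   with `namespace`, `terms` (character) and `edges`
#'   (tibble `child`, `parent`, `type`).
#' @export
read_ontology <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  in_term <- FALSE
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id) && !isTRUE(cur$obsolete)) {
      terms[[cur$id]] <- cur
    }
    terms
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character(), types = character())
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      if (startsWith(ln, "id:")) {
        cur$id <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "namespace:")) {
        cur$namespace <- trimws(sub("^namespace:", "", ln))
      } else if (startsWith(ln, "is_a:")) {
        tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        cur$parents <- c(cur$parents, tgt)
        cur$types <- c(cur$types, "is_a")
      } else if (startsWith(ln, "relationship:")) {
        rest <- trimws(sub("^relationship:", "", ln))
        if (startsWith(rest, "part_of")) {
          tgt <- trimws(sub("!.*$", "", sub("^part_of", "", rest)))
          cur$parents <- c(cur$parents, tgt)
          cur$types <- c(cur$types, "part_of")
        }
      } else if (startsWith(ln, "is_obsolete:")) {
        cur$obsolete <- grepl("true", ln, fixed = TRUE)
      }
    }
  }
  terms <- flush(cur, terms)
  if (length(terms) == 0) abort("no usable [Term] stanzas found")

  namespaces <- vapply(terms, function(t) t$namespace %||% "unknown", "")
  ids <- names(terms)
  out <- list()
  for (ns in unique(namespaces)) {
    ns_ids <- ids[namespaces == ns]
    ch <- unlist(lapply(ns_ids, function(i)
      rep(i, length(terms[[i]]$parents))), use.names = FALSE) %||% character()
    pa <- unlist(lapply(ns_ids, function(i) terms[[i]]$parents),
                 use.names = FALSE) %||% character()
    ty <- unlist(lapply(ns_ids, function(i) terms[[i]]$types),
                 use.names = FALSE) %||% character()
    # drop edges to obsolete/absent parents outside the namespace's term set
    keep <- pa %in% ns_ids
    edges <- tibble::tibble(child = ch[keep], parent = pa[keep], type = ty[keep])
    dag <- new_ontology_dag(ns, ns_ids, edges)
    out[[ns]] <- dag
  }
  structure(out, class = "ontology_set")
}

new_ontology_dag <- function(namespace, terms, edges) {
  dag <- structure(list(namespace = namespace, terms = terms, edges = edges),
                   class = "ontology_dag")
  cyc <- find_cycle_member(dag)
  if (!is.null(cyc)) abort(sprintf("ontology namespace '%s' contains a cycle through term %s",
                                   namespace, cyc))
  dag
}

# Kahn's algorithm; returns NULL if acyclic, else one term on a cycle
find_cycle_member <- function(dag) {
  if (nrow(dag$edges) == 0) return(NULL)
  g <- igraph::graph_from_data_frame(dag$edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = dag$terms))
  if (igraph::is_dag(g)) return(NULL)
  # locate a vertex in a non-trivial strongly connected component
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize > 1)[1]
  igraph::V(g)$name[comp$membership == big][1]
}

#' Write an ontology set as OBO 1.2
#' @param ontology an `ontology_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (dag in ontology) {
    for (tm in dag$terms) {
      writeLines("[Term]", con)
      writeLines(paste0("id: ", tm), con)
      writeLines(paste0("namespace: ", dag$namespace), con)
      e <- dag$edges[dag$edges$child == tm, , drop = FALSE]
      for (i in seq_len(nrow(e))) {
        if (e$type[i] == "is_a") {
          writeLines(paste0("is_a: ", e$parent[i]), con)
        } else {
          writeLines(paste0("relationship: part_of ", e$parent[i]), con)
        }
      }
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Read a two-column association table (gene to term, or phenotype to gene)
#'
#' @param path path to a 2-column TSV (`key`, `value`).
#' @param ontology optional `ontology_set`; when supplied, term values absent
#'   from every namespace raise an error.
#' @return an `annotation_table`: named list mapping each key to its character
#'   vector of values (empty-set keys are retained if listed with an empty
#'   value field).
#' @export
read_annotations <- function(path, ontology = NULL) {
  parsed <- read_tsv_lines(path)
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 2)
  if (length(bad) > 0) {
    abort(sprintf("malformed association line %d: expected 2 fields",
                  parsed$lineno[bad[1]]))
  }
  key <- vapply(fields, `[[`, "", 1L)
  val <- vapply(fields, `[[`, "", 2L)
  if (!is.null(ontology)) {
    known <- unlist(lapply(ontology, `[[`, "terms"), use.names = FALSE)
    missing <- setdiff(val, known)
    if (length(missing) > 0) {
      abort(sprintf("annotation term(s) not in ontology: %s",
                    paste(utils::head(missing, 5), collapse = ", ")))
    }
  }
  out <- split(val, key)
  out <- lapply(out, unique)
  structure(out[order(names(out), method = "radix")], class = "annotation_table")
}

#' Write an association table
#' @param annots an `annotation_table` (named list of character vectors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annots, path) {
  keys <- rep(names(annots), lengths(annots))
  vals <- unlist(annots, use.names = FALSE)
  writeLines(paste(keys, vals, sep = "\t"), path)
  invisible(path)
}

#' Read phenotype-gene associations
#'
#' 2-column TSV (`phenotype`, `gene`). Returns both directions of the mapping
#' as named lists so either side is queryable in constant expected time.
#'
#' @param path path to a TSV file.
#' @return a `phenotype_assoc`: list with `ph2g` (phenotype -> genes) and
#'   `g2ph` (gene -> phenotypes).
#' @export
read_phenotype_assoc <- function(path) {
  tab <- read_annotations(path)
  ph <- rep(names(tab), lengths(tab))
  g <- unlist(tab, use.names = FALSE)
  g2ph <- lapply(split(ph, g), unique)
  structure(list(ph2g = unclass(tab),
                 g2ph = g2ph[order(names(g2ph), method = "radix")]),
            class = "phenotype_assoc")
}

#' Write phenotype-gene associations
#' @param assoc a `phenotype_assoc`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_assoc <- function(assoc, path) {
  write_annotations(assoc$ph2g, path)
}

#' Read a phenotype similarity matrix
#'
#' Labeled square TSV. Cells asymmetric beyond 1e-6 raise an error; values
#' outside \[0, 1\] are clipped with a warning; the diagonal is forced to 1
#' (with a warning when it was not).
#'
#' @param path path to a TSV file.
#' @return a `pheno_sim`: list with `phenotypes` and the symmetric `sims`
#'   matrix (unit diagonal); attribute `n_clipped` counts adjusted cells.
#' @export
read_pheno_sim <- function(path) {
  parsed <- read_tsv_lines(path)
  if (length(parsed$lines) < 2) abort("similarity file is empty")
  header <- strsplit(parsed$lines[1], "\t", fixed = TRUE)[[1]][-1]
  body <- strsplit(parsed$lines[-1], "\t", fixed = TRUE)
  rows <- vapply(body, `[[`, "", 1L)
  if (!identical(rows, header)) abort("similarity matrix rows and columns disagree")
  m <- do.call(rbind, lapply(body, function(f) as.numeric(f[-1])))
  if (any(is.na(m))) abort("non-numeric similarity cell")
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6) abort(sprintf("similarity matrix asymmetric (max deviation %.3g)", asym))
  m <- (m + t(m)) / 2
  n_clipped <- sum(m < 0 | m > 1)
  if (n_clipped > 0) {
    warn(sprintf("%d similarity cells clipped to [0, 1]", n_clipped))
    m <- pmin(pmax(m, 0), 1)
  }
  if (any(diag(m) != 1)) {
    warn(sprintf("%d diagonal cells reset to 1", sum(diag(m) != 1)))
    diag(m) <- 1
  }
  new_pheno_sim(header, m, n_clipped = n_clipped)
}

new_pheno_sim <- function(phenotypes, sims, n_clipped = 0L) {
  rownames(sims) <- phenotypes
  colnames(sims) <- phenotypes
  structure(list(phenotypes = phenotypes, sims = sims),
            class = "pheno_sim", n_clipped = as.integer(n_clipped))
}

#' Write a phenotype similarity matrix
#' @param sim a `pheno_sim`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pheno_sim <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("phenotype", sim$phenotypes), collapse = "\t"), con)
  body <- apply(sim$sims, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(sim$phenotypes, body, sep = "\t"), con)
  invisible(path)
}

#' Read a positive gene list (one id per line)
#' @param path path to a text file.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  parsed <- read_tsv_lines(path)
  ids <- trimws(parsed$lines)
  stopifnot_gene_ids(ids)
  if (anyDuplicated(ids)) abort("duplicate gene id in gene list")
  ids
}

#' Write a gene list
#' @param genes character vector of gene ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Write / read a run report as JSON
#'
#' Reports are serialized with stable (insertion) key order and full numeric
#' precision so that a write/read round trip is the identity on the report
#' list.
#'
#' @param report a named list (nested lists, numbers, strings).
#' @param path output path.
#' @return for `write_report`, `path` invisibly; for `read_report`, the list.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}
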