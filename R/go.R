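#' Parse an OBO 1.2 ontology into a DAG
#'
#' Reads `[Term]` stanzas (id, name, namespace, is_a, is_obsolete) and
#' builds an acyclic single-namespace DAG restricted by default to
#' biological_process. Obsolete terms are dropped with a warning; a cyclic
#' is_a graph is an error.
#'
#' @param path OBO file.
#' @param namespace namespace to keep (`NULL` for all).
#' @return Object of class `go_dag`: list with `terms` (data.frame `id`,
#'   `name`, `namespace`), `parents`/`children` (named lists of character
#'   vectors), `roots`, and a topological order `topo` (parents before
#'   children) with per-term `depth` (longest path from a root).
#' @export
load_obo <- function(path, namespace = "biological_process") {
  lines <- readLines(path)
  term_starts <- which(lines == "[Term]")
  terms <- list(); edges <- list()
  for (s in term_starts) {
    e <- s + 1L
    rec <- list(is_a = character(0), obsolete = FALSE)
    while (e <= length(lines) && lines[e] != "" && !grepl("^\\[", lines[e])) {
      ln <- lines[e]
      if (startsWith(ln, "id: ")) rec$id <- sub("^id: ", "", ln)
      if (startsWith(ln, "name: ")) rec$name <- sub("^name: ", "", ln)
      if (startsWith(ln, "namespace: ")) rec$namespace <- sub("^namespace: ", "", ln)
      if (startsWith(ln, "is_a: ")) {
        rec$is_a <- c(rec$is_a, sub(" !.*$", "", sub("^is_a: ", "", ln)))
      }
      if (startsWith(ln, "is_obsolete: true")) rec$obsolete <- TRUE
      e <- e + 1L
    }
    if (is.null(rec$id)) next
    terms[[rec$id]] <- rec
  }
  obs <- names(terms)[vapply(terms, `[[`, TRUE, "obsolete")]
  if (length(obs)) {
    warning("dropping ", length(obs), " obsolete term(s)")
    terms[obs] <- NULL
  }
  if (!is.null(namespace)) {
    keep <- vapply(terms, function(t) identical(t$namespace, namespace), TRUE)
    terms <- terms[keep]
  }
  ids <- names(terms)
  parents <- lapply(terms, function(t) intersect(t$is_a, ids))
  go_dag(data.frame(
    id = ids,
    name = vapply(terms, function(t) t$name %||% "", ""),
    namespace = vapply(terms, function(t) t$namespace %||% "", ""),
    stringsAsFactors = FALSE
  ), parents)
}

#' Build a DAG from a term table and parent lists
#'
#' @param terms data.frame `id`, `name`, `namespace`.
#' @param parents named list: term id -> character vector of parent ids.
#' @return Object of class `go_dag` (see [load_obo()]).
#' @export
go_dag <- function(terms, parents) {
  ids <- terms$id
  parents <- parents[ids]
  names(parents) <- ids
  parents <- lapply(parents, function(p) intersect(p %||% character(0), ids))
  children <- setNames(vector("list", length(ids)), ids)
  for (id in ids) for (p in parents[[id]]) {
    children[[p]] <- c(children[[p]], id)
  }
  # Kahn topological sort (parents first); failure = cycle
  indeg <- vapply(parents, length, 0L)
  queue <- sort(ids[indeg == 0L])
  topo <- character(0)
  depth <- setNames(rep(0L, length(ids)), ids)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    topo <- c(topo, v)
    for (ch in children[[v]]) {
      depth[ch] <- max(depth[ch], depth[v] + 1L)
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- sort(c(queue, ch))
    }
  }
  if (length(topo) != length(ids)) stop("cyclic is_a graph")
  structure(list(terms = terms, parents = parents, children = children,
                 roots = ids[vapply(parents, length, 0L) == 0L],
                 topo = topo, depth = depth),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms, %d root(s), max depth %d\n",
              nrow(x$terms), length(x$roots), max(x$depth)))
  invisible(x)
}

# all ancestors (excluding the term itself)
dag_ancestors <- function(dag, id) {
  out <- character(0)
  frontier <- dag$parents[[id]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    frontier <- setdiff(frontier, out)
  }
  out
}

#' Propagate gene annotations up the DAG (true-path rule)
#'
#' A gene annotated to a term is annotated to all its ancestors. Returns
#' the per-term annotated gene sets after propagation; idempotent.
#'
#' @param gene2go data.frame with columns `gene_id` and `term`.
#' @param dag a [go_dag()].
#' @return named list: term id -> character vector of gene ids. Attribute
#'   `direct` holds the unpropagated sets.
#' @export
annotate_genes <- function(gene2go, dag) {
  unknown <- setdiff(unique(gene2go$term), dag$terms$id)
  if (length(unknown)) {
    stop("gene2go references unknown term(s): ",
         paste(head(unknown, 5), collapse = ", "))
  }
  direct <- lapply(setNames(dag$terms$id, dag$terms$id), function(t) {
    sort(unique(gene2go$gene_id[gene2go$term == t]))
  })
  ann <- direct
  # children before parents: reverse topological order
  for (t in rev(dag$topo)) {
    for (p in dag$parents[[t]]) {
      ann[[p]] <- union(ann[[p]], ann[[t]])
    }
  }
  ann <- lapply(ann, sort)
  attr(ann, "direct") <- direct
  ann
}

#' Classic Fisher GO over-representation test
#'
#' One-sided (over-representation) Fisher exact test per term of the 2x2
#' table (in term vs not) x (candidate vs not) over the gene universe. Only
#' terms with at least `min_sig` candidate genes are reported.
#'
#' @param candidates character vector of candidate gene ids (subset of
#'   `universe`).
#' @param universe all scored gene ids.
#' @param ann propagated annotation sets ([annotate_genes()]).
#' @param min_sig minimum candidate genes in the term.
#' @return data.frame: `term`, `n_annotated`, `n_candidate`, `odds_ratio`,
#'   `p`.
#' @export
classic_fisher <- function(candidates, universe, ann, min_sig = 5L) {
  stopifnot(all(candidates %in% universe))
  out <- lapply(names(ann), function(t) {
    genes <- intersect(ann[[t]], universe)
    sig <- length(intersect(genes, candidates))
    if (sig < min_sig) return(NULL)
    tab <- matrix(c(sig, length(genes) - sig,
                    length(candidates) - sig,
                    length(universe) - length(genes) -
                      length(candidates) + sig), 2, 2)
    f <- fisher.test(tab, alternative = "greater")
    data.frame(term = t, n_annotated = length(genes), n_candidate = sig,
               odds_ratio = unname(f$estimate), p = f$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame(term = character(),
                                      n_annotated = integer(),
                                      n_candidate = integer(),
                                      odds_ratio = numeric(), p = numeric()))
  res[order(res$p, res$term), , drop = FALSE]
}

#' Score-based Kolmogorov-Smirnov GO enrichment
#'
#' Per term, a one-sided two-sample KS test comparing the Z_ST scores of
#' the term's genes against all remaining scored genes, with the
#' alternative that the term's scores are stochastically larger (high Z_ST
#' = differentiated). Terms with fewer than `min_size` scored annotated
#' genes, or with an empty complement, are skipped.
#'
#' @param scores named numeric vector of gene scores (names = gene ids).
#' @param ann propagated annotation sets ([annotate_genes()]).
#' @param min_size minimum scored annotated genes.
#' @return data.frame: `term`, `n_annotated`, `statistic`, `p`.
#' @export
ks_score_test <- function(scores, ann, min_size = 5L) {
  stopifnot(!is.null(names(scores)))
  out <- lapply(names(ann), function(t) {
    genes <- intersect(ann[[t]], names(scores))
    if (length(genes) < min_size) return(NULL)
    rest <- setdiff(names(scores), genes)
    if (!length(rest)) return(NULL)
    # "less": the CDF of x lies below that of y <=> x stochastically larger
    kt <- suppressWarnings(ks.test(scores[genes], scores[rest],
                                   alternative = "less"))
    data.frame(term = t, n_annotated = length(genes),
               statistic = unname(kt$statistic), p = kt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame(term = character(),
                                      n_annotated = integer(),
                                      statistic = numeric(), p = numeric()))
  res[order(res$p, res$term), , drop = FALSE]
}

#' The elim decorrelation algorithm
#'
#' Processes terms bottom-up (children strictly before parents; ties in
#' depth broken by term id). Each term is tested on its *current* gene set
#' with the base test (Fisher over-representation or score KS); when the
#' p-value falls below `cutoff`, the term's originally annotated genes are
#' removed from the current sets of all its ancestors before those are
#' tested. This favours the most specific significant terms and discounts
#' ancestors whose signal is inherited.
#'
#' @param ann propagated annotation sets ([annotate_genes()]).
#' @param dag the [go_dag()].
#' @param base `"fisher"` or `"ks"`.
#' @param cutoff elimination significance threshold.
#' @param candidates,universe for the Fisher base test.
#' @param scores named score vector for the KS base test.
#' @param min_sig,min_size the base tests' minimum-size rules.
#' @return data.frame with per-term `p_elim` alongside the classic
#'   (uneliminated) `p_classic`, `n_annotated`, `n_used` (genes left when
#'   the term was tested).
#' @export
elim_test <- function(ann, dag, base = c("fisher", "ks"), cutoff = 0.01,
                      candidates = NULL, universe = NULL, scores = NULL,
                      min_sig = 5L, min_size = 5L) {
  base <- match.arg(base)
  test_one <- function(genes) {
    if (base == "fisher") {
      genes <- intersect(genes, universe)
      sig <- length(intersect(genes, candidates))
      if (sig < min_sig) return(NULL)
      tab <- matrix(c(sig, length(genes) - sig,
                      length(candidates) - sig,
                      length(universe) - length(genes) -
                        length(candidates) + sig), 2, 2)
      list(p = fisher.test(tab, alternative = "greater")$p.value, n = sig,
           n_used = length(genes))
    } else {
      genes <- intersect(genes, names(scores))
      if (length(genes) < min_size) return(NULL)
      rest <- setdiff(names(scores), genes)
      if (!length(rest)) return(NULL)
      p <- suppressWarnings(ks.test(scores[genes], scores[rest],
                                    alternative = "less"))$p.value
      list(p = p, n = length(genes), n_used = length(genes))
    }
  }
  current <- lapply(ann, identity)
  # bottom-up: decreasing depth, term id as tie-break
  ids <- names(ann)
  ord <- ids[order(-dag$depth[ids], ids)]
  rows <- list()
  for (t in ord) {
    res <- test_one(current[[t]])
    classic <- test_one(ann[[t]])
    if (!is.null(res)) {
      rows[[t]] <- data.frame(
        term = t, n_annotated = length(ann[[t]]), n_used = res$n_used,
        p_elim = res$p,
        p_classic = if (!is.null(classic)) classic$p else NA_real_,
        stringsAsFactors = FALSE
      )
      if (res$p < cutoff) {
        for (anc in dag_ancestors(dag, t)) {
          current[[anc]] <- setdiff(current[[anc]], ann[[t]])
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame(term = character(),
                                      n_annotated = integer(),
                                      n_used = integer(),
                                      p_elim = numeric(),
                                      p_classic = numeric()))
  rownames(res) <- NULL
  res[order(res$p_elim, res$term), , drop = FALSE]
}
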