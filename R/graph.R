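#' Assemble the disease-trajectory graph
#'
#' Nodes are disease categories annotated with the PheWAS hazard ratio and
#' case count; directed edges are confirmed D1 -> D2 pairs annotated with the
#' odds ratio, pair count and stage p-values. Cycles are permitted at this
#' stage but reported (a 2-cycle can arise only from differing tie
#' patterns); pruning leaves cyclic edges untouched.
#'
#' @param phewas_results table from [run_phewas()] covering every pair
#'   endpoint.
#' @param pairs confirmed pairs (rows of [run_pair_inference()] with
#'   `confirmed == TRUE`, or any table with `d1`, `d2`, `or`, `n_both`,
#'   `binom_p`, `logit_p`).
#' @param nodes extra categories to carry as (possibly isolated) nodes;
#'   default: the pair endpoints only.
#' @return a `trajectory_graph`: list with `nodes` and `edges` data.tables.
#' @export
assemble_graph <- function(phewas_results, pairs, nodes = character()) {
  cats <- sort(unique(c(pairs$d1, pairs$d2, nodes)))
  miss <- setdiff(cats, phewas_results$outcome)
  if (length(miss)) {
    stop("assemble_graph: pair endpoint(s) without a PheWAS annotation: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(pairs$d1 == pairs$d2)) {
    stop("assemble_graph: self-loop pair supplied", call. = FALSE)
  }
  idx <- match(cats, phewas_results$outcome)
  nodes <- data.table::data.table(
    category = cats,
    hr = phewas_results$hr[idx],
    n_cases = phewas_results$n_cases_exposed[idx])
  edges <- data.table::data.table(
    d1 = as.character(pairs$d1), d2 = as.character(pairs$d2),
    or = pairs$or %||% rep(NA_real_, nrow(pairs)),
    n_both = pairs$n_both %||% rep(NA_integer_, nrow(pairs)),
    binom_p = pairs$binom_p %||% rep(NA_real_, nrow(pairs)),
    logit_p = pairs$logit_p %||% rep(NA_real_, nrow(pairs)),
    pruned = FALSE)
  data.table::setorderv(edges, c("d1", "d2"))
  g <- structure(list(nodes = nodes, edges = edges),
                 class = "trajectory_graph")
  cyc <- cyclic_edges(g)
  if (any(cyc)) {
    message(sprintf("assemble_graph: %d edge(s) participate in directed cycles",
                    sum(cyc)))
  }
  g
}

#' @export
print.trajectory_graph <- function(x, ...) {
  cat(sprintf("<trajectory_graph> %d nodes, %d edges (%d pruned)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$pruned)))
  invisible(x)
}

#' Unpruned edges of a trajectory graph
#' @param g a `trajectory_graph`.
#' @export
active_edges <- function(g) g$edges[!g$edges$pruned]

as_igraph <- function(g, active_only = TRUE) {
  e <- if (active_only) active_edges(g) else g$edges
  igraph::graph_from_data_frame(
    as.data.frame(e[, c("d1", "d2")]),
    directed = TRUE,
    vertices = data.frame(name = g$nodes$category))
}

cyclic_edges <- function(g) {
  if (!nrow(g$edges)) return(logical(0))
  ig <- as_igraph(g, active_only = FALSE)
  comp <- igraph::components(ig, mode = "strong")$membership
  comp[g$edges$d1] == comp[g$edges$d2]
}

reachable <- function(g, active_only = TRUE) {
  # category x category logical reachability (paths of length >= 1)
  n <- nrow(g$nodes)
  if (!n) return(matrix(logical(0), 0, 0))
  ig <- as_igraph(g, active_only = active_only)
  d <- igraph::distances(ig, mode = "out")
  d <- d[g$nodes$category, g$nodes$category, drop = FALSE]
  r <- is.finite(d) & d > 0
  dimnames(r) <- list(g$nodes$category, g$nodes$category)
  r
}

#' Transitive pruning of shortcut edges
#'
#' Deletes the connecting line D1 -> D3 whenever the trajectory already runs
#' D1 -> D2 -> D3: on the acyclic part of the graph this is exactly the
#' transitive reduction (an edge is a shortcut iff an alternative directed
#' path of length >= 2 links its endpoints), and reachability is preserved.
#' Edges inside directed cycles are exempt and reported, never silently
#' deleted. Pruned edges are retained with `pruned = TRUE` so exports can
#' show both views; [active_edges()] and exports default to the pruned view.
#'
#' @param g a `trajectory_graph`.
#' @return the graph with shortcut edges flagged; idempotent.
#' @export
transitive_prune <- function(g) {
  e <- g$edges
  if (!nrow(e)) return(g)
  keep <- !e$pruned
  cyc <- rep(FALSE, nrow(e))
  cyc[keep] <- {
    gg <- g; gg$edges <- e[keep]
    cyclic_edges(gg)
  }
  # condensation: collapse strongly connected components, reduce between them
  ig <- as_igraph(g)
  comp <- igraph::components(ig, mode = "strong")$membership
  cid <- comp[g$nodes$category]
  names(cid) <- g$nodes$category
  inter <- keep & !cyc
  if (any(inter)) {
    ce <- unique(data.frame(a = cid[e$d1[inter]], b = cid[e$d2[inter]]))
    cg <- igraph::graph_from_data_frame(
      ce, directed = TRUE,
      vertices = data.frame(name = sort(unique(as.integer(cid)))))
    d <- igraph::distances(cg, mode = "out")
    redundant <- vapply(which(inter), function(i) {
      a <- as.character(cid[e$d1[i]]); b <- as.character(cid[e$d2[i]])
      # shortcut iff some intermediate component lies strictly between a and b
      mids <- setdiff(rownames(d)[is.finite(d[a, ]) & d[a, ] > 0], b)
      any(is.finite(d[mids, b]) & d[mids, b] > 0)
    }, logical(1))
    e$pruned[which(inter)[redundant]] <- TRUE
  }
  g$edges <- e
  g
}

#' Layer the pruned trajectory graph
#'
#' On the pruned, acyclic part: sources (in-degree 0) are "original"
#' diseases, sinks (out-degree 0) "terminal", the rest "intermediary";
#' isolated nodes are "original-terminal" and nodes inside directed cycles
#' are "cyclic" and excluded from layering. Both the direct-successor count
#' and the distinct-descendant count are emitted, since "mediated downstream
#' diseases" tallies can be read either way.
#'
#' @param g a pruned `trajectory_graph`.
#' @return data.table: `category`, `layer`, `n_direct`, `n_descendants`,
#'   `depth` (longest path from a source; NA for cyclic nodes).
#' @export
layer_nodes <- function(g) {
  cats <- g$nodes$category
  e <- active_edges(g)
  ig <- as_igraph(g)
  comp <- igraph::components(ig, mode = "strong")
  cyclic <- comp$csize[comp$membership] > 1
  names(cyclic) <- names(comp$membership)
  indeg <- table(factor(e$d2, levels = cats))
  outdeg <- table(factor(e$d1, levels = cats))
  r <- reachable(g)
  layer <- ifelse(cyclic[cats], "cyclic",
           ifelse(indeg[cats] == 0 & outdeg[cats] == 0, "original-terminal",
           ifelse(indeg[cats] == 0, "original",
           ifelse(outdeg[cats] == 0, "terminal", "intermediary"))))
  depth <- rep(NA_real_, length(cats))
  acy <- !cyclic[cats]
  if (any(acy)) {
    sub <- igraph::induced_subgraph(ig, cats[acy])
    topo <- names(igraph::topo_sort(sub, mode = "out"))
    dp <- setNames(rep(0, length(topo)), topo)
    for (v in topo) {
      preds <- names(igraph::neighbors(sub, v, mode = "in"))
      if (length(preds)) dp[v] <- max(dp[preds]) + 1
    }
    depth[match(topo, cats)] <- dp[topo]
  }
  data.table::data.table(
    category = cats, layer = as.character(layer),
    n_direct = as.integer(outdeg[cats]),
    n_descendants = as.integer(rowSums(r)),
    depth = depth)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

num_attr <- function(x) {
  ifelse(is.na(x), "", formatC(x, format = "g", digits = 17))
}

#' Export a trajectory graph
#'
#' Writes bit-stable artifacts: `graph.graphml` (typed GraphML),
#' `graph.json` (node-link JSON), and flat `nodes.tsv` / `edges.tsv`.
#' Node attributes: `hr`, `n_cases`; edge attributes: `or`, `n_both`,
#' `binom_p`, `logit_p`, `pruned`. The TSV edge table keeps pruned shortcut
#' edges with their flag; GraphML/JSON carry the pruned view plus the flag.
#'
#' @param g a `trajectory_graph`.
#' @param dir output directory (created if needed).
#' @param formats subset of `c("graphml", "json", "tsv")`.
#' @return invisible character vector of files written.
#' @export
export_graph <- function(g, dir, formats = c("graphml", "json", "tsv")) {
  bad <- setdiff(formats, c("graphml", "json", "tsv"))
  if (length(bad)) {
    stop("export_graph: unknown format(s) ", paste(bad, collapse = ", "),
         "; supported: graphml, json, tsv", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  nodes <- g$nodes[order(g$nodes$category)]
  edges <- g$edges[order(g$edges$d1, g$edges$d2)]
  if ("graphml" %in% formats) {
    f <- file.path(dir, "graph.graphml")
    con <- file(f, "wb")  # binary mode: stable LF line endings
    w <- function(...) cat(..., "\n", sep = "", file = con)
    w('<?xml version="1.0" encoding="UTF-8"?>')
    w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
    w('  <key id="hr" for="node" attr.name="hr" attr.type="double"/>')
    w('  <key id="n_cases" for="node" attr.name="n_cases" attr.type="long"/>')
    w('  <key id="or" for="edge" attr.name="or" attr.type="double"/>')
    w('  <key id="n_both" for="edge" attr.name="n_both" attr.type="long"/>')
    w('  <key id="binom_p" for="edge" attr.name="binom_p" attr.type="double"/>')
    w('  <key id="logit_p" for="edge" attr.name="logit_p" attr.type="double"/>')
    w('  <key id="pruned" for="edge" attr.name="pruned" attr.type="boolean"/>')
    w('  <graph edgedefault="directed">')
    for (i in seq_len(nrow(nodes))) {
      w(sprintf('    <node id="%s">', xml_escape(nodes$category[i])))
      w(sprintf('      <data key="hr">%s</data>', num_attr(nodes$hr[i])))
      w(sprintf('      <data key="n_cases">%s</data>', num_attr(nodes$n_cases[i])))
      w('    </node>')
    }
    for (i in seq_len(nrow(edges))) {
      w(sprintf('    <edge source="%s" target="%s">',
                xml_escape(edges$d1[i]), xml_escape(edges$d2[i])))
      w(sprintf('      <data key="or">%s</data>', num_attr(edges$or[i])))
      w(sprintf('      <data key="n_both">%s</data>', num_attr(edges$n_both[i])))
      w(sprintf('      <data key="binom_p">%s</data>', num_attr(edges$binom_p[i])))
      w(sprintf('      <data key="logit_p">%s</data>', num_attr(edges$logit_p[i])))
      w(sprintf('      <data key="pruned">%s</data>',
                tolower(as.character(edges$pruned[i]))))
      w('    </edge>')
    }
    w('  </graph>')
    w('</graphml>')
    close(con)
    files <- c(files, f)
  }
  if ("json" %in% formats) {
    f <- file.path(dir, "graph.json")
    jsonlite::write_json(
      list(directed = TRUE,
           nodes = as.data.frame(nodes),
           links = as.data.frame(edges)),
      f, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    files <- c(files, f)
  }
  if ("tsv" %in% formats) {
    fn <- file.path(dir, "nodes.tsv"); fe <- file.path(dir, "edges.tsv")
    data.table::fwrite(nodes, fn, sep = "\t", eol = "\n")
    data.table::fwrite(edges, fe, sep = "\t", eol = "\n")
    files <- c(files, fn, fe)
  }
  invisible(files)
}

#' Re-import an exported GraphML trajectory graph
#'
#' Parses the GraphML written by [export_graph()] back into a
#' `trajectory_graph`; export followed by import is the identity.
#'
#' @param path path to `graph.graphml`.
#' @export
import_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  getd <- function(node, key) {
    v <- xml2::xml_text(xml2::xml_find_first(node, sprintf("data[@key='%s']", key)))
    if (is.na(v) || v == "") NA_character_ else v
  }
  nn <- xml2::xml_find_all(doc, ".//node")
  nodes <- data.table::data.table(
    category = xml2::xml_attr(nn, "id"),
    hr = as.numeric(vapply(nn, getd, "", key = "hr")),
    n_cases = as.integer(vapply(nn, getd, "", key = "n_cases")))
  ee <- xml2::xml_find_all(doc, ".//edge")
  edges <- data.table::data.table(
    d1 = xml2::xml_attr(ee, "source"),
    d2 = xml2::xml_attr(ee, "target"),
    or = as.numeric(vapply(ee, getd, "", key = "or")),
    n_both = as.integer(vapply(ee, getd, "", key = "n_both")),
    binom_p = as.numeric(vapply(ee, getd, "", key = "binom_p")),
    logit_p = as.numeric(vapply(ee, getd, "", key = "logit_p")),
    pruned = vapply(ee, getd, "", key = "pruned") == "true")
  structure(list(nodes = nodes, edges = edges), class = "trajectory_graph")
}
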