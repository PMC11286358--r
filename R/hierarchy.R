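#' Assembly hierarchies
#'
#' An `assembly_hierarchy` is a rooted directed acyclic graph of protein
#' assemblies. Assemblies contain other assemblies ("default" edges) and carry
#' direct gene annotations ("gene" edges). It is the structural blueprint of a
#' visible neural network: each assembly becomes a neuron block whose inputs
#' are its K child assemblies and its M "additional" genes (direct genes whose
#' products occur in no descendant assembly).
#'
#' @name assembly_hierarchy
#' @keywords internal
NULL

new_hierarchy <- function(assemblies, root, annotated = FALSE) {
  structure(
    list(assemblies = assemblies, root = root, annotated = annotated),
    class = "assembly_hierarchy"
  )
}

#' Build an assembly hierarchy from an edge table
#'
#' @param edges A data frame with columns `parent`, `child`, `type`. Rows with
#'   `type = "default"` nest assembly `child` inside assembly `parent`; rows
#'   with `type = "gene"` annotate gene symbol `child` directly to assembly
#'   `parent`. Gene symbols are whitespace-trimmed and matched case-sensitively.
#' @return A validated, structurally annotated `assembly_hierarchy`.
#' @export
hierarchy_from_edges <- function(edges) {
  stopifnot(is.data.frame(edges))
  need <- c("parent", "child", "type")
  if (!all(need %in% names(edges))) {
    stop("edge table must have columns parent, child, type", call. = FALSE)
  }
  edges <- tibble::as_tibble(edges[need])
  edges$parent <- trimws(as.character(edges$parent))
  edges$child <- trimws(as.character(edges$child))
  edges$type <- as.character(edges$type)

  bad <- setdiff(unique(edges$type), c("default", "gene"))
  if (length(bad) > 0) {
    stop("unknown edge type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }

  aedges <- edges[edges$type == "default", , drop = FALSE]
  gedges <- edges[edges$type == "gene", , drop = FALSE]
  if (any(aedges$parent == aedges$child)) {
    stop("cycle detected: self-loop on ",
      aedges$parent[aedges$parent == aedges$child][1],
      call. = FALSE
    )
  }

  ids <- unique(c(aedges$parent, aedges$child, gedges$parent))
  if (length(ids) == 0) stop("no assemblies found in edge table", call. = FALSE)

  assemblies <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    assemblies[[id]] <- list(
      id = id,
      children = unique(aedges$child[aedges$parent == id]),
      direct_genes = unique(gedges$child[gedges$parent == id])
    )
  }

  has_parent <- ids %in% aedges$child
  roots <- ids[!has_parent]
  if (length(roots) != 1) {
    stop(
      "hierarchy must have exactly one root; found ",
      length(roots), " (", paste(utils::head(roots, 5), collapse = ", "), ")",
      call. = FALSE
    )
  }

  h <- new_hierarchy(assemblies, root = roots)
  topo_order(h) # errors on cycles
  annotate_structure(h)
}

#' Read an assembly hierarchy from a 3-column edge-list file
#'
#' The file is tab-delimited with no header: parent id, child id, edge type
#' (`default` for assembly containment, `gene` for gene annotation) — the
#' DDOT-style ontology interchange format.
#'
#' @param path Path to the edge-list file.
#' @return An annotated `assembly_hierarchy`.
#' @export
parse_hierarchy <- function(path) {
  edges <- utils::read.table(
    path,
    sep = "\t", header = FALSE, stringsAsFactors = FALSE,
    col.names = c("parent", "child", "type"), quote = "",
    comment.char = ""
  )
  if (nrow(edges) == 0) stop("empty edge-list file: ", path, call. = FALSE)
  hierarchy_from_edges(edges)
}

#' Write an assembly hierarchy back to an edge-list file
#'
#' @param h An `assembly_hierarchy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(h, path) {
  stopifnot(inherits(h, "assembly_hierarchy"))
  tab <- hierarchy_edges(h)
  utils::write.table(
    tab, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Edge table of a hierarchy
#'
#' @param h An `assembly_hierarchy`.
#' @return A tibble with columns `parent`, `child`, `type`.
#' @export
hierarchy_edges <- function(h) {
  stopifnot(inherits(h, "assembly_hierarchy"))
  purrr::map_dfr(h$assemblies, function(a) {
    dplyr::bind_rows(
      if (length(a$children) > 0) {
        tibble::tibble(parent = a$id, child = a$children, type = "default")
      },
      if (length(a$direct_genes) > 0) {
        tibble::tibble(parent = a$id, child = a$direct_genes, type = "gene")
      }
    )
  })
}

#' Export a hierarchy as a GMT gene-set file
#'
#' One line per assembly: id, display name, then the assembly's total gene set
#' (direct genes plus all descendant genes), tab-separated.
#'
#' @param h An annotated `assembly_hierarchy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_gmt <- function(h, path) {
  h <- ensure_annotated(h)
  lines <- purrr::map_chr(h$assemblies, function(a) {
    paste(c(a$id, a$id, sort(a$genes_total)), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

# Kahn topological order over assembly-containment edges, children first.
# Errors on cycles (including self-loops).
topo_order <- function(h) {
  ids <- names(h$assemblies)
  kids <- purrr::map(h$assemblies, "children")
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (id in ids) {
    for (c in kids[[id]]) {
      if (c == id) stop("cycle detected at assembly ", id, call. = FALSE)
      indeg[c] <- indeg[c] + 1L
    }
  }
  queue <- ids[indeg == 0]
  out <- character(0)
  while (length(queue) > 0) {
    id <- queue[1]
    queue <- queue[-1]
    out <- c(out, id)
    for (c in kids[[id]]) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0) queue <- c(queue, c)
    }
  }
  if (length(out) != length(ids)) {
    stop("cycle detected in assembly hierarchy", call. = FALSE)
  }
  rev(out) # children before parents
}

#' Annotate a hierarchy with structural quantities
#'
#' Computes, for every assembly: `K` (number of child assemblies), the total
#' gene set (direct genes united with all descendants'), the `M` additional
#' genes (direct genes absent from every descendant's total gene set), and
#' `depth_layer` (leaves are layer 1; a parent sits one layer above its
#' deepest child, so the root occupies the maximum layer).
#'
#' @param h An `assembly_hierarchy`.
#' @return The hierarchy with per-assembly fields `K`, `M`, `m_genes`,
#'   `genes_total`, `depth_layer` filled in, plus `gene_universe` and
#'   `n_layers` at the top level.
#' @export
annotate_structure <- function(h) {
  stopifnot(inherits(h, "assembly_hierarchy"))
  ord <- topo_order(h)
  for (id in ord) {
    a <- h$assemblies[[id]]
    if (length(a$children) == 0) {
      desc_genes <- character(0)
      a$depth_layer <- 1L
    } else {
      desc_genes <- unique(unlist(
        purrr::map(h$assemblies[a$children], "genes_total")
      ))
      a$depth_layer <- 1L + max(purrr::map_int(
        h$assemblies[a$children], "depth_layer"
      ))
    }
    a$genes_total <- unique(c(a$direct_genes, desc_genes))
    a$m_genes <- setdiff(a$direct_genes, desc_genes)
    a$K <- length(a$children)
    a$M <- length(a$m_genes)
    h$assemblies[[id]] <- a
  }
  h$gene_universe <- unique(unlist(
    purrr::map(h$assemblies, "direct_genes")
  ))
  h$n_layers <- h$assemblies[[h$root]]$depth_layer
  h$annotated <- TRUE
  h
}

ensure_annotated <- function(h) {
  stopifnot(inherits(h, "assembly_hierarchy"))
  if (!isTRUE(h$annotated)) h <- annotate_structure(h)
  h
}

#' Restrict a hierarchy to a gene panel and prune small assemblies
#'
#' Gene annotations are first restricted to `panel`. Assemblies whose total
#' panel-gene count falls below `min_genes` are then removed; both the
#' children and the direct gene annotations of a removed assembly are
#' re-attached to its nearest retained ancestor, so no panel gene covered by a
#' retained branch is lost and retained totals are unchanged (which makes the
#' operation idempotent).
#'
#' @param h An `assembly_hierarchy`.
#' @param panel Character vector of gene symbols to keep.
#' @param min_genes Minimum total panel-gene count for an assembly to survive
#'   (default 5).
#' @return A filtered, annotated `assembly_hierarchy`.
#' @export
filter_by_panel <- function(h, panel, min_genes = 5) {
  h <- ensure_annotated(h)
  panel <- unique(trimws(as.character(panel)))
  stopifnot(length(panel) > 0, min_genes >= 1)

  restricted <- h
  for (id in names(restricted$assemblies)) {
    a <- restricted$assemblies[[id]]
    a$direct_genes <- intersect(a$direct_genes, panel)
    restricted$assemblies[[id]] <- a
  }
  restricted$annotated <- FALSE
  restricted <- annotate_structure(restricted)

  keep <- purrr::map_lgl(
    restricted$assemblies,
    function(a) length(a$genes_total) >= min_genes
  )
  if (!keep[[restricted$root]]) {
    stop(
      "root assembly has fewer than ", min_genes,
      " panel genes; nothing to model", call. = FALSE
    )
  }

  # For a retained assembly, replace each dropped child by that child's
  # retained descendants, and absorb the dropped subtree's direct genes.
  resolve <- function(id) {
    out_children <- character(0)
    out_genes <- character(0)
    for (c in restricted$assemblies[[id]]$children) {
      if (keep[[c]]) {
        out_children <- c(out_children, c)
      } else {
        sub <- resolve(c)
        out_children <- c(out_children, sub$children)
        out_genes <- c(
          out_genes, restricted$assemblies[[c]]$direct_genes, sub$genes
        )
      }
    }
    list(children = unique(out_children), genes = unique(out_genes))
  }

  kept_ids <- names(restricted$assemblies)[keep]
  assemblies <- stats::setNames(vector("list", length(kept_ids)), kept_ids)
  for (id in kept_ids) {
    res <- resolve(id)
    assemblies[[id]] <- list(
      id = id,
      children = res$children,
      direct_genes = unique(c(
        restricted$assemblies[[id]]$direct_genes, res$genes
      ))
    )
  }
  annotate_structure(new_hierarchy(assemblies, root = restricted$root))
}

#' Jaccard similarity of two gene sets
#'
#' @param a,b Character vectors (gene sets); at least one must be nonempty.
#' @return `|a intersect b| / |a union b|`, a fraction in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    stop("Jaccard similarity of two empty sets is undefined", call. = FALSE)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Total gene sets of every assembly
#'
#' @param h An annotated `assembly_hierarchy`.
#' @return Named list of character vectors, one total gene set per assembly.
#' @export
assembly_gene_sets <- function(h) {
  h <- ensure_annotated(h)
  purrr::map(h$assemblies, "genes_total")
}

#' @export
print.assembly_hierarchy <- function(x, ...) {
  x <- ensure_annotated(x)
  cat(
    "<assembly_hierarchy> ", length(x$assemblies), " assemblies, ",
    length(x$gene_universe), " genes, ", x$n_layers, " layers; root ",
    x$root, "\n",
    sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an assembly hierarchy
#'
#' @param x An `assembly_hierarchy`.
#' @param ... Unused.
#' @return A tibble with one row per assembly: id, K, M, depth_layer,
#'   direct and total gene counts, and whether it is the root.
#' @method tidy assembly_hierarchy
#' @export
tidy.assembly_hierarchy <- function(x, ...) {
  x <- ensure_annotated(x)
  purrr::map_dfr(x$assemblies, function(a) {
    tibble::tibble(
      assembly = a$id,
      K = a$K,
      M = a$M,
      depth_layer = a$depth_layer,
      n_direct_genes = length(a$direct_genes),
      n_total_genes = length(a$genes_total),
      is_root = a$id == x$root
    )
  })
}
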