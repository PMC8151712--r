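#' Collapse aligned sequences into haplotypes
#'
#' Sequences identical on the retained columns are grouped into one
#' haplotype. Haplotype ids `h1, h2, ...` are assigned by order of first
#' appearance in the input, so a fixed input order yields reproducible
#' labels. Under the default complete-deletion policy the retained columns
#' are those free of gaps/ambiguity codes across the subset, which makes
#' within-haplotype distances exactly zero.
#'
#' @inheritParams segregating_sites
#' @return A `haplotype_table`: tibble with `hap_id`, `size`, `members`
#'   (list column of specimen ids) and `representative` (full sequence of the
#'   first member), plus `marker_name` and `retained` (logical column mask)
#'   attributes.
#' @export
collapse_haplotypes <- function(aln, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  if (nrow(aln) == 0) abort("cannot collapse an empty alignment")
  m <- seq_matrix(aln)
  retained <- if (policy == "complete") complete_columns(m) else rep(TRUE, ncol(m))
  key <- apply(m[, retained, drop = FALSE], 1, paste, collapse = "")
  first <- !duplicated(key)
  hap_of <- match(key, key[first])
  out <- tibble(
    hap_id = paste0("h", seq_len(sum(first))),
    size = as.integer(tabulate(hap_of, nbins = sum(first))),
    members = purrr::map(seq_len(sum(first)), function(k) {
      aln$specimen_id[hap_of == k]
    }),
    representative = aln$seq[first]
  )
  structure(out,
    marker_name = marker_name(aln), retained = retained, policy = policy,
    class = c("haplotype_table", class(out))
  )
}

#' Expand a haplotype table back to specimen membership
#'
#' @param haplotypes A `haplotype_table`.
#' @return Tibble `specimen_id`, `hap_id`.
#' @export
haplotype_members <- function(haplotypes) {
  tidyr::unnest(
    select(as_tibble(haplotypes), "hap_id", specimen_id = "members"),
    "specimen_id"
  )
}

#' Mutational-step distance matrix between haplotypes
#'
#' Hamming distances between haplotype representatives over columns where
#' both carry unambiguous bases (after the collapse policy's column
#' retention).
#'
#' @param haplotypes A `haplotype_table` with at least 2 haplotypes.
#' @return Symmetric integer matrix with hap ids as dimnames.
#' @export
haplotype_distances <- function(haplotypes) {
  if (nrow(haplotypes) < 2) abort("need at least 2 haplotypes for distances")
  retained <- attr(haplotypes, "retained")
  m <- do.call(rbind, strsplit(haplotypes$representative, "", fixed = TRUE))
  m <- m[, retained, drop = FALSE]
  k <- nrow(m)
  d <- matrix(0L, k, k, dimnames = list(haplotypes$hap_id, haplotypes$hap_id))
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      ok <- is_unambiguous(m[i, ]) & is_unambiguous(m[j, ])
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok])
    }
  }
  d
}

# Union-find for Kruskal.
uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}

#' Minimum spanning haplotype network
#'
#' Builds a minimum spanning tree over haplotypes with mutational steps as
#' edge weights (Kruskal's algorithm; ties broken deterministically by the
#' haplotype pair's position in the table, i.e. lexicographic in assignment
#' order). Non-tree edges that could replace a tree edge of equal weight
#' (their weight equals the maximum edge weight on the tree path between
#' their endpoints) are retained as flagged alternatives, so the result is a
#' network rather than a strict tree.
#'
#' @param x A `haplotype_table`, or a symmetric distance matrix.
#' @param sizes Haplotype sizes when `x` is a matrix (defaults to 1).
#' @return A `haplotype_msn`: list with `nodes` (tibble `hap_id`, `size`) and
#'   `edges` (tibble `from`, `to`, `steps`, `alternative`).
#' @export
build_msn <- function(x, sizes = NULL) {
  if (inherits(x, "haplotype_table")) {
    nodes <- tibble(hap_id = x$hap_id, size = x$size)
    d <- if (nrow(x) >= 2) haplotype_distances(x) else NULL
    marker <- attr(x, "marker_name")
  } else {
    d <- x
    ids <- rownames(d) %||% paste0("h", seq_len(nrow(d)))
    nodes <- tibble(hap_id = ids, size = as.integer(sizes %||% rep(1L, nrow(d))))
    marker <- NULL
  }
  k <- nrow(nodes)
  empty_edges <- tibble(
    from = character(), to = character(),
    steps = integer(), alternative = logical()
  )
  if (k < 2) {
    return(structure(list(nodes = nodes, edges = empty_edges),
      marker_name = marker, class = "haplotype_msn"
    ))
  }
  cand <- tidyr::expand_grid(i = seq_len(k), j = seq_len(k)) |>
    filter(.data$i < .data$j) |>
    mutate(w = d[cbind(.data$i, .data$j)]) |>
    arrange(.data$w, .data$i, .data$j)
  parent <- seq_len(k)
  in_tree <- logical(nrow(cand))
  for (e in seq_len(nrow(cand))) {
    ri <- uf_find(parent, cand$i[e])
    rj <- uf_find(parent, cand$j[e])
    if (ri != rj) {
      parent[ri] <- rj
      in_tree[e] <- TRUE
    }
  }
  tree <- cand[in_tree, ]
  # adjacency of the tree for path-maximum queries
  adj <- vector("list", k)
  for (e in seq_len(nrow(tree))) {
    i <- tree$i[e]
    j <- tree$j[e]
    adj[[i]] <- rbind(adj[[i]], c(j, tree$w[e]))
    adj[[j]] <- rbind(adj[[j]], c(i, tree$w[e]))
  }
  path_max <- function(from, to) {
    # DFS on the tree, tracking the largest edge weight on the way
    stack <- list(list(node = from, mx = -Inf))
    seen <- logical(k)
    seen[from] <- TRUE
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (cur$node == to) {
        return(cur$mx)
      }
      nb <- adj[[cur$node]]
      if (!is.null(nb)) {
        for (r in seq_len(nrow(nb))) {
          if (!seen[nb[r, 1]]) {
            seen[nb[r, 1]] <- TRUE
            stack[[length(stack) + 1]] <- list(node = nb[r, 1], mx = max(cur$mx, nb[r, 2]))
          }
        }
      }
    }
    abort("tree is not connected (internal error)")
  }
  alt <- cand[!in_tree, ]
  alt_keep <- logical(nrow(alt))
  for (e in seq_len(nrow(alt))) {
    alt_keep[e] <- alt$w[e] <= path_max(alt$i[e], alt$j[e])
  }
  edges <- bind_rows(
    mutate(tree, alternative = FALSE),
    mutate(alt[alt_keep, ], alternative = TRUE)
  ) |>
    arrange(.data$alternative, .data$w, .data$i, .data$j) |>
    mutate(
      from = nodes$hap_id[.data$i], to = nodes$hap_id[.data$j],
      steps = as.integer(.data$w)
    ) |>
    select("from", "to", "steps", "alternative")
  structure(list(nodes = nodes, edges = edges),
    marker_name = marker, class = "haplotype_msn"
  )
}

#' @export
print.haplotype_msn <- function(x, ...) {
  mk <- attr(x, "marker_name")
  cat("<haplotype_msn>",
    if (!is.null(mk)) paste0(" ", mk), ": ",
    nrow(x$nodes), " haplotypes, ",
    sum(!x$edges$alternative), " tree edges",
    if (any(x$edges$alternative)) {
      paste0(" (+", sum(x$edges$alternative), " alternative)")
    }, "\n",
    sep = ""
  )
  if (nrow(x$edges) > 0) {
    apply(x$edges, 1, function(e) {
      cat(
        "  ", e[["from"]], "--", e[["to"]], ": ", e[["steps"]], " steps",
        if (e[["alternative"]] == "TRUE") " [alt]", "\n",
        sep = ""
      )
    })
  }
  invisible(x)
}

#' Annotate network nodes with region composition and strain
#'
#' Adds per-haplotype Africa/Asia member counts (and, when classification
#' calls are supplied, the haplotype's strain label) to the node table, and
#' records which haplotypes are shared between the two continents.
#'
#' @param msn A `haplotype_msn` built from `haplotypes`.
#' @param haplotypes The `haplotype_table` the network was built from.
#' @param samples Specimen metadata with `region`.
#' @param calls Optional classification tibble (`specimen_id`, `strain`,
#'   `subgroup`); the haplotype is annotated with its members' unique
#'   strain/subgroup label.
#' @return The `haplotype_msn` with `Africa`, `Asia` (and optionally
#'   `strain`) node columns and a `shared` attribute tibble listing
#'   haplotypes present on both continents.
#' @export
annotate_regions <- function(msn, haplotypes, samples, calls = NULL) {
  mem <- haplotype_members(haplotypes) |>
    left_join(select(samples, "specimen_id", "region"), by = "specimen_id")
  comp <- mem |>
    count(.data$hap_id, .data$region) |>
    tidyr::pivot_wider(
      names_from = "region", values_from = "n", values_fill = 0L
    )
  for (rg in c("Africa", "Asia")) {
    if (!rg %in% names(comp)) comp[[rg]] <- 0L
  }
  nodes <- left_join(msn$nodes, select(comp, "hap_id", "Africa", "Asia"),
    by = "hap_id"
  ) |>
    mutate(
      Africa = dplyr::coalesce(.data$Africa, 0L),
      Asia = dplyr::coalesce(.data$Asia, 0L)
    )
  if (!is.null(calls)) {
    strain_of <- mem |>
      left_join(
        select(calls, "specimen_id", "strain", "subgroup"),
        by = "specimen_id"
      ) |>
      group_by(.data$hap_id) |>
      summarise(strain = paste(
        unique(stats::na.omit(
          ifelse(is.na(.data$subgroup), .data$strain, .data$subgroup)
        )),
        collapse = "/"
      ))
    nodes <- left_join(nodes, strain_of, by = "hap_id")
  }
  msn$nodes <- nodes
  attr(msn, "shared") <- filter(nodes, .data$Africa > 0 & .data$Asia > 0)
  msn
}

#' @rdname annotate_regions
#' @export
shared_haplotypes <- function(msn) {
  attr(msn, "shared") %||%
    abort("network has no region annotation; run annotate_regions() first")
}

#' Convert a haplotype network to igraph
#'
#' @param msn A `haplotype_msn`.
#' @param include_alternatives Keep flagged alternative edges (default TRUE).
#' @return An `igraph` graph with `size` vertex and `steps`/`alternative`
#'   edge attributes.
#' @export
as_igraph <- function(msn, include_alternatives = TRUE) {
  edges <- msn$edges
  if (!include_alternatives) edges <- filter(edges, !.data$alternative)
  igraph::graph_from_data_frame(
    d = as.data.frame(edges),
    directed = FALSE,
    vertices = as.data.frame(msn$nodes)
  )
}

#' Export a haplotype network
#'
#' `write_msn_graphml()` writes GraphML (via igraph); `write_msn_edges()` and
#' `write_msn_nodes()` write plain TSV tables.
#'
#' @param msn A `haplotype_msn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msn_graphml <- function(msn, path) {
  igraph::write_graph(as_igraph(msn), path, format = "graphml")
  invisible(path)
}

#' @rdname write_msn_graphml
#' @export
write_msn_edges <- function(msn, path) {
  readr::write_tsv(msn$edges, path)
  invisible(path)
}

#' @rdname write_msn_graphml
#' @export
write_msn_nodes <- function(msn, path) {
  readr::write_tsv(msn$nodes, path)
  invisible(path)
}

#' Plot a haplotype network
#'
#' Nodes are scaled by haplotype size and, when the network carries region
#' annotation, coloured by the fraction of African members; tree edges are
#' solid with mutational-step labels, alternative edges dashed. Layout is
#' Fruchterman-Reingold with a fixed seed for reproducibility.
#'
#' @param object A `haplotype_msn`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot haplotype_msn
#' @export
autoplot.haplotype_msn <- function(object, seed = 42L, ...) {
  g <- as_igraph(object, include_alternatives = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    left_join(select(nodes, "hap_id", "x", "y"), by = c(from = "hap_id")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(select(nodes, "hap_id", "x", "y"), by = c(to = "hap_id")) |>
    rename(x1 = "x", y1 = "y")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        linetype = .data$alternative
      ),
      colour = "grey40"
    ) +
    ggplot2::geom_label(
      data = mutate(edges, mx = (.data$x0 + .data$x1) / 2, my = (.data$y0 + .data$y1) / 2),
      ggplot2::aes(x = .data$mx, y = .data$my, label = .data$steps),
      size = 3, label.size = 0
    )
  if ("Africa" %in% names(nodes)) {
    p <- p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(
        x = .data$x, y = .data$y, size = .data$size,
        colour = .data$Africa / (.data$Africa + .data$Asia)
      )
    ) +
      ggplot2::scale_colour_gradient(
        name = "African fraction",
        low = "#2166AC", high = "#B2182B", limits = c(0, 1)
      )
  } else {
    p <- p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$size)
    )
  }
  p +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$hap_id),
      vjust = -1.2, size = 3
    ) +
    ggplot2::scale_size_area(name = "specimens", max_size = 12) +
    ggplot2::scale_linetype_manual(
      values = c(`FALSE` = "solid", `TRUE` = "dashed"), guide = "none"
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(title = attr(object, "marker_name"))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
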