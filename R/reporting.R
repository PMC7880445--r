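#' Shared/unshared topology comparison of two structural graphs
#'
#' Overlays the compound-sharing graphs of two organisms built over the same
#' universe. Every pathway node present in at least one organism, and every
#' structural edge of either graph, is labelled with its ownership:
#' \code{"both"}, \code{"a_only"} or \code{"b_only"} — the information the
#' original colour-coded network overlay conveys.
#'
#' @param net_a,net_b \code{two_level_network}s over the same universe and
#'   ubiquitous list.
#' @return An object of class \code{topology_comparison}: a list with
#'   \code{org_a}, \code{org_b}, \code{nodes} (data frame: \code{pathway},
#'   \code{title}, \code{ownership}) and \code{edges} (data frame:
#'   \code{from}, \code{to}, \code{ownership}; \code{from < to} in universe
#'   order).
#' @export
topology_comparison <- function(net_a, net_b) {
  check_comparable(net_a, net_b)
  universe <- net_a$universe
  in_a <- net_a$status != "absent"
  in_b <- net_b$status != "absent"
  nodes_idx <- in_a | in_b
  ownership <- ifelse(in_a & in_b, "both", ifelse(in_a, "a_only", "b_only"))
  nodes <- data.frame(
    pathway = universe[nodes_idx],
    title = vapply(universe[nodes_idx], function(p) {
      if (nzchar(net_a$titles[p])) net_a$titles[[p]] else net_b$titles[[p]]
    }, character(1)),
    ownership = ownership[nodes_idx],
    stringsAsFactors = FALSE, row.names = NULL
  )

  edge_key <- function(net) {
    pres <- net$universe[net$status != "absent"]
    keys <- character(0)
    if (length(pres) > 1L) {
      for (a in seq_along(pres)[-length(pres)]) {
        for (b in seq.int(a + 1L, length(pres))) {
          if (net$matrix[pres[a], pres[b]] > 0L) {
            keys <- c(keys, paste(pres[a], pres[b], sep = "|"))
          }
        }
      }
    }
    keys
  }
  ka <- edge_key(net_a)
  kb <- edge_key(net_b)
  all_keys <- sort(union(ka, kb))
  parts <- strsplit(all_keys, "|", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[`, character(1), 1L),
    to = vapply(parts, `[`, character(1), 2L),
    ownership = ifelse(
      all_keys %in% ka & all_keys %in% kb, "both",
      ifelse(all_keys %in% ka, "a_only", "b_only")
    ),
    stringsAsFactors = FALSE, row.names = NULL
  )

  structure(
    list(org_a = net_a$org, org_b = net_b$org, nodes = nodes, edges = edges),
    class = "topology_comparison"
  )
}

#' @export
print.topology_comparison <- function(x, ...) {
  cat(sprintf(
    "Topology comparison %s vs %s: %d nodes, %d edges\n",
    x$org_a, x$org_b, nrow(x$nodes), nrow(x$edges)
  ))
  cat("  node ownership:", paste(
    names(table(x$nodes$ownership)), table(x$nodes$ownership),
    sep = "=", collapse = ", "
  ), "\n")
  if (nrow(x$edges)) {
    cat("  edge ownership:", paste(
      names(table(x$edges$ownership)), table(x$edges$ownership),
      sep = "=", collapse = ", "
    ), "\n")
  }
  invisible(x)
}

#' Export a topology comparison as a colourable graph
#'
#' GraphML or DOT export of the overlaid structural graphs with an
#' \code{ownership} attribute (\code{both} / \code{a_only} / \code{b_only})
#' on every node and edge, so a graph viewer can colour shared and unshared
#' parts differently. Element order is fixed; repeated exports are
#' byte-identical.
#'
#' @param tc a \code{topology_comparison}.
#' @param file output path.
#' @param format \code{"graphml"} or \code{"dot"}.
#' @return the path, invisibly.
#' @export
export_topology <- function(tc, file, format = c("graphml", "dot")) {
  stopifnot(inherits(tc, "topology_comparison"))
  format <- match.arg(format)
  g <- igraph::make_empty_graph(n = nrow(tc$nodes), directed = FALSE)
  igraph::V(g)$name <- tc$nodes$pathway
  igraph::V(g)$title <- tc$nodes$title
  igraph::V(g)$ownership <- tc$nodes$ownership
  if (nrow(tc$edges)) {
    g <- igraph::add_edges(g, as.vector(rbind(tc$edges$from, tc$edges$to)))
    igraph::E(g)$ownership <- tc$edges$ownership
  }
  igraph::write_graph(g, file, format = format)
  invisible(file)
}

#' Write a pairwise comparison as CSV
#'
#' Emits two CSV files: the per-pathway table (columns \code{pathway},
#' \code{title}, \code{sim_s}, \code{sim_p}, \code{sim_s_case},
#' \code{sim_p_case}, \code{union_size}, sorted by pathway number) at
#' \code{path}, and a summary file \code{<stem>_summary.csv} holding the
#' organism codes, the mode, \code{n} and the four global indexes. Numbers
#' are written at full precision; any display rounding belongs to the
#' rendering layer. Output is deterministic, so re-exporting the same
#' comparison is byte-identical.
#'
#' @param cmp a \code{pairwise_comparison}.
#' @param path path of the per-pathway CSV; the summary lands next to it.
#' @return character vector of the two paths, invisibly.
#' @export
write_comparison <- function(cmp, path) {
  stopifnot(inherits(cmp, "pairwise_comparison"))
  rows <- cmp$rows
  header <- "pathway,title,sim_s,sim_p,sim_s_case,sim_p_case,union_size"
  body <- vapply(seq_len(nrow(rows)), function(i) {
    paste(
      csv_quote(rows$pathway[i]), csv_quote(rows$title[i]),
      num_fmt(rows$sim_s[i]), num_fmt(rows$sim_p[i]),
      rows$sim_s_case[i], rows$sim_p_case[i],
      num_fmt(rows$union_size[i]),
      sep = ","
    )
  }, character(1))
  writeLines(c(header, body), path)

  summary_path <- sub("(\\.[Cc][Ss][Vv])?$", "_summary.csv", path)
  if (identical(summary_path, path)) summary_path <- paste0(path, "_summary.csv")
  writeLines(
    c(
      "key,value",
      paste0("org_a,", csv_quote(cmp$org_a)),
      paste0("org_b,", csv_quote(cmp$org_b)),
      paste0("mode,", cmp$mode),
      paste0("n,", cmp$n),
      paste0("psim,", num_fmt(cmp$psim)),
      paste0("psim_w,", num_fmt(cmp$psim_w)),
      paste0("ssim,", num_fmt(cmp$ssim)),
      paste0("csim,", num_fmt(cmp$csim))
    ),
    summary_path
  )
  invisible(c(path, summary_path))
}

csv_quote <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Read and write comparison-run configuration files
#'
#' A comparison run is configured by a small key-value file (one
#' \code{key = value} per line, \code{#} comments, list values
#' comma-separated) selecting the reference-pathway universe, the
#' ubiquitous-compound exclusion list, the reaction-collection mode, the
#' global indexes to report and the output directory.
#'
#' @param path configuration file path.
#' @return \code{read_config}: a list with elements \code{universe},
#'   \code{ubiquitous}, \code{mode}, \code{indexes}, \code{out_dir}
#'   (defaults filled in where keys are missing).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("bad configuration line (expected key = value): '", ln, "'",
        call. = FALSE
      )
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    cfg[[key]] <- val
  }
  split_list <- function(x) {
    if (is.null(x) || !nzchar(x)) return(character(0))
    trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  }
  out <- list(
    universe = split_list(cfg$universe),
    ubiquitous = if (is.null(cfg$ubiquitous)) {
      default_ubiquitous()
    } else {
      split_list(cfg$ubiquitous)
    },
    mode = if (is.null(cfg$mode)) "set" else cfg$mode,
    indexes = if (is.null(cfg$indexes)) {
      c("psim", "psim_w", "ssim", "csim")
    } else {
      split_list(cfg$indexes)
    },
    out_dir = if (is.null(cfg$out_dir)) "." else cfg$out_dir
  )
  if (!out$mode %in% c("set", "multiset")) {
    stop("configuration: mode must be 'set' or 'multiset'", call. = FALSE)
  }
  bad <- setdiff(out$indexes, c("psim", "psim_w", "ssim", "csim"))
  if (length(bad)) {
    stop("configuration: unknown indexes ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' @rdname read_config
#' @param cfg a configuration list as returned by [read_config()].
#' @return \code{write_config}: the path, invisibly.
#' @export
write_config <- function(cfg, path) {
  writeLines(
    c(
      paste0("universe = ", paste(cfg$universe, collapse = ",")),
      paste0("ubiquitous = ", paste(cfg$ubiquitous, collapse = ",")),
      paste0("mode = ", cfg$mode),
      paste0("indexes = ", paste(cfg$indexes, collapse = ",")),
      paste0("out_dir = ", cfg$out_dir)
    ),
    path
  )
  invisible(path)
}
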