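#' Build the two-level representation of one organism's metabolism
#'
#' Assembles the functional level (per-pathway reaction multisets, with a
#' presence classification) and the structural level (the compound-sharing
#' graph, stored as the square adjacency matrix with the diagonal encoding)
#' from the parsed KGML records of one organism.
#'
#' Each pathway of the universe is classified as \code{"absent"} (no KGML
#' record), \code{"physical"} (a record exists but holds no reactions — a
#' membrane/physical-mechanism pathway that KEGG represents only as an
#' image) or \code{"reaction"} (at least one reaction). Two present pathways
#' are joined by a structural edge when they share at least one compound
#' after removal of the ubiquitous list; the matrix stores the count of
#' shared non-ubiquitous compounds in the off-diagonal cells. The diagonal
#' encodes presence and connectivity: \code{-1} absent, \code{0} present but
#' isolated, \code{k > 0} present with exactly \code{k} neighbours.
#'
#' The universe is put in ascending pathway-number order so that matrices
#' built for different organisms over the same universe are position-aligned
#' cell by cell.
#'
#' @param records named list over pathway numbers as returned by
#'   [load_organism()]: \code{pathway_record} or \code{NULL} per number.
#' @param universe character vector of 5-digit reference-pathway numbers.
#' @param ubiquitous compound accessions excluded from the edge rule;
#'   defaults to [default_ubiquitous()].
#' @param org organism code; taken from the first record when omitted.
#' @return An object of class \code{two_level_network}: a list with
#'   \code{org}, \code{universe}, \code{status}, \code{titles},
#'   \code{reactions} (named list of multisets), \code{compounds} (named
#'   list of filtered compound sets), \code{matrix} (integer adjacency
#'   matrix with the diagonal convention) and \code{ubiquitous}.
#' @export
build_network <- function(records, universe, ubiquitous = default_ubiquitous(),
                          org = NULL) {
  universe <- check_universe(universe)
  ubiquitous <- sort(unique(as.character(ubiquitous)))

  extra <- setdiff(names(records), universe)
  if (length(extra)) {
    stop(
      "records outside the configured universe: ",
      paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(org)) {
    for (rec in records) {
      if (!is.null(rec)) {
        org <- rec$org
        break
      }
    }
    if (is.null(org)) org <- "unknown"
  }

  n <- length(universe)
  status <- stats::setNames(rep("absent", n), universe)
  titles <- stats::setNames(rep("", n), universe)
  reactions <- stats::setNames(
    rep(list(structure(integer(0), names = character(0))), n), universe
  )
  compounds <- stats::setNames(rep(list(character(0)), n), universe)

  for (p in universe) {
    rec <- records[[p]]
    if (is.null(rec)) next
    status[p] <- if (length(rec$reactions) == 0L) "physical" else "reaction"
    titles[p] <- rec$title
    reactions[[p]] <- rec$reactions
    compounds[[p]] <- sort(setdiff(rec$compounds, ubiquitous))
  }

  m <- matrix(0L, n, n, dimnames = list(universe, universe))
  present <- universe[status != "absent"]
  if (length(present) > 1L) {
    for (a in seq_along(present)[-length(present)]) {
      for (b in seq.int(a + 1L, length(present))) {
        i <- present[a]
        j <- present[b]
        shared <- length(intersect(compounds[[i]], compounds[[j]]))
        m[i, j] <- m[j, i] <- as.integer(shared)
      }
    }
  }
  for (p in universe) {
    m[p, p] <- if (status[p] == "absent") {
      -1L
    } else {
      as.integer(sum(m[p, universe != p] > 0L))
    }
  }

  structure(
    list(
      org = org, universe = universe, status = status, titles = titles,
      reactions = reactions, compounds = compounds, matrix = m,
      ubiquitous = ubiquitous
    ),
    class = "two_level_network"
  )
}

#' @export
print.two_level_network <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("reaction", "physical", "absent")))
  cat(
    sprintf(
      "Two-level metabolic network of '%s' over %d reference pathways\n",
      x$org, length(x$universe)
    ),
    sprintf(
      "  %d reaction, %d physical, %d absent; %d structural edges\n",
      tab[["reaction"]], tab[["physical"]], tab[["absent"]],
      sum(x$matrix[upper.tri(x$matrix)] > 0L)
    )
  )
  invisible(x)
}

#' Neighbours of a pathway node in the structural graph
#'
#' The set of edges incident to a pathway node, each edge identified by its
#' far-endpoint pathway number. The size of this set equals the diagonal
#' entry of the adjacency matrix whenever that entry is positive.
#'
#' @param net a \code{two_level_network}.
#' @param p a pathway number present in the network.
#' @return character vector of neighbour pathway numbers (possibly empty).
#' @export
edge_set <- function(net, p) {
  stopifnot(inherits(net, "two_level_network"))
  if (!p %in% net$universe) {
    stop("pathway ", p, " is not in the universe", call. = FALSE)
  }
  if (net$status[p] == "absent") {
    stop(
      "pathway ", p, " is absent from organism '", net$org,
      "'; it has no structural node",
      call. = FALSE
    )
  }
  row <- net$matrix[p, ]
  names(row)[row > 0L & names(row) != p]
}

## igraph of the present pathways, vertices in universe order, edges i<j;
## shared-compound counts kept as edge weights
structural_igraph <- function(net) {
  present <- net$universe[net$status != "absent"]
  g <- igraph::make_empty_graph(n = length(present), directed = FALSE)
  igraph::V(g)$name <- present
  igraph::V(g)$title <- unname(net$titles[present])
  if (length(present) > 1L) {
    ends <- character(0)
    weights <- integer(0)
    for (a in seq_along(present)[-length(present)]) {
      for (b in seq.int(a + 1L, length(present))) {
        w <- net$matrix[present[a], present[b]]
        if (w > 0L) {
          ends <- c(ends, present[a], present[b])
          weights <- c(weights, w)
        }
      }
    }
    if (length(weights)) {
      g <- igraph::add_edges(g, ends)
      igraph::E(g)$weight <- weights
    }
  }
  g
}

#' Export the structural graph
#'
#' Writes the compound-sharing graph of one organism in GraphML or DOT
#' format. Nodes are the present pathways (named by pathway number, with the
#' title as an attribute); edges carry the shared non-ubiquitous compound
#' count as a \code{weight} attribute. Element order is fixed (universe
#' order), so repeated exports of the same network are byte-identical.
#'
#' @param net a \code{two_level_network}.
#' @param file output path.
#' @param format \code{"graphml"} or \code{"dot"}.
#' @return the output path, invisibly.
#' @export
export_graph <- function(net, file, format = c("graphml", "dot")) {
  stopifnot(inherits(net, "two_level_network"))
  format <- match.arg(format)
  g <- structural_igraph(net)
  igraph::write_graph(g, file, format = format)
  invisible(file)
}

#' Write the adjacency matrix as TSV
#'
#' Serialises the structural adjacency matrix with a header row and column
#' of pathway numbers. The diagonal encoding (-1 absent / 0 isolated /
#' k neighbours) is preserved exactly.
#'
#' @param net a \code{two_level_network}.
#' @param file output path.
#' @return the output path, invisibly.
#' @export
write_adjacency <- function(net, file) {
  stopifnot(inherits(net, "two_level_network"))
  header <- paste(c("pathway", colnames(net$matrix)), collapse = "\t")
  body <- vapply(
    rownames(net$matrix),
    function(p) paste(c(p, net$matrix[p, ]), collapse = "\t"),
    character(1)
  )
  writeLines(c(header, body), file)
  invisible(file)
}
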