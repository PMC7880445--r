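## Multiset arithmetic over named integer count vectors.
## Intersection = per-accession min of counts, union = per-accession max,
## cardinality = sum of counts. In set mode counts collapse to presence.

ms_cardinality <- function(x, mode) {
  if (mode == "set") length(x) else sum(x)
}

ms_inter_union <- function(a, b, mode) {
  keys <- sort(union(names(a), names(b)))
  ca <- stats::setNames(rep(0L, length(keys)), keys)
  cb <- ca
  ca[names(a)] <- a
  cb[names(b)] <- b
  if (mode == "set") {
    ca <- pmin(ca, 1L)
    cb <- pmin(cb, 1L)
  }
  c(inter = sum(pmin(ca, cb)), union = sum(pmax(ca, cb)))
}

check_comparable <- function(net_a, net_b) {
  stopifnot(
    inherits(net_a, "two_level_network"),
    inherits(net_b, "two_level_network")
  )
  if (!identical(net_a$universe, net_b$universe)) {
    stop("the two networks were built over different pathway universes",
      call. = FALSE
    )
  }
  if (!identical(net_a$ubiquitous, net_b$ubiquitous)) {
    stop("the two networks use different ubiquitous-compound lists",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Pathway (functional-level) similarity of one reference pathway
#'
#' Case-based similarity of the reaction content of one reference pathway
#' between two organisms:
#' \describe{
#'   \item{case1}{present in exactly one organism: 0.}
#'   \item{case2}{physical pathway (no reactions) in both: 1 — the index
#'     only records that the function is present in both metabolisms.}
#'   \item{case3}{reaction pathway in both: the Jaccard index
#'     \eqn{|R \cap R'| / |R \cup R'|} of the two reaction collections, as
#'     sets (\code{mode = "set"}) or multisets (\code{mode = "multiset"},
#'     min-of-counts intersection and max-of-counts union).}
#'   \item{case3_mixed}{a KGML record exists in both organisms but only one
#'     holds reactions. This physical-versus-reaction mix falls between the
#'     defined cases; it is scored 0 (the empty-versus-non-empty Jaccard)
#'     and flagged with its own label so reports can surface it.}
#' }
#'
#' @param net_a,net_b \code{two_level_network}s over the same universe and
#'   ubiquitous list.
#' @param p a pathway number present in at least one of the two networks.
#' @param mode \code{"set"} or \code{"multiset"}.
#' @return list with \code{value} in \eqn{[0, 1]}, \code{case} label, and
#'   \code{union_size} (the cardinality of \eqn{R \cup R'}, the weight used
#'   by the weighted global index).
#' @export
sim_pathway <- function(net_a, net_b, p, mode = c("set", "multiset")) {
  mode <- match.arg(mode)
  check_comparable(net_a, net_b)
  sa <- net_a$status[p]
  sb <- net_b$status[p]
  if (is.na(sa) || is.na(sb)) {
    stop("pathway ", p, " is not in the universe", call. = FALSE)
  }
  if (sa == "absent" && sb == "absent") {
    stop("pathway ", p, " is absent from both organisms", call. = FALSE)
  }
  if (sa == "absent" || sb == "absent") {
    present <- if (sa == "absent") net_b else net_a
    return(list(
      value = 0,
      case = "case1",
      union_size = ms_cardinality(present$reactions[[p]], mode)
    ))
  }
  if (sa == "physical" && sb == "physical") {
    return(list(value = 1, case = "case2", union_size = 0L))
  }
  iu <- ms_inter_union(net_a$reactions[[p]], net_b$reactions[[p]], mode)
  if (sa != sb) {
    ## one physical, one reaction: empty-vs-non-empty Jaccard
    return(list(value = 0, case = "case3_mixed", union_size = unname(iu["union"])))
  }
  list(
    value = unname(iu["inter"] / iu["union"]),
    case = "case3",
    union_size = unname(iu["union"])
  )
}

#' Structure (topological-level) similarity of one reference pathway
#'
#' Case-based similarity of the local neighbourhood of one pathway node in
#' the two structural compound-sharing graphs:
#' \describe{
#'   \item{case1}{node in exactly one graph: 0.}
#'   \item{case2}{isolated in both graphs (shares no non-ubiquitous compound
#'     with any other pathway in either organism): 1.}
#'   \item{case3}{isolated in one graph, degree \eqn{k > 0} in the other:
#'     \eqn{1 / (1 + k)}, where \eqn{k} is the degree of the connected
#'     occurrence.}
#'   \item{case4}{connected in both: the Jaccard index of the two incident
#'     edge sets, edges identified by their far-endpoint pathway number.}
#' }
#'
#' @inheritParams sim_pathway
#' @return list with \code{value} in \eqn{[0, 1]} and \code{case} label.
#' @export
sim_structure <- function(net_a, net_b, p) {
  check_comparable(net_a, net_b)
  sa <- net_a$status[p]
  sb <- net_b$status[p]
  if (is.na(sa) || is.na(sb)) {
    stop("pathway ", p, " is not in the universe", call. = FALSE)
  }
  if (sa == "absent" && sb == "absent") {
    stop("pathway ", p, " is absent from both organisms", call. = FALSE)
  }
  if (sa == "absent" || sb == "absent") {
    return(list(value = 0, case = "case1"))
  }
  ea <- edge_set(net_a, p)
  eb <- edge_set(net_b, p)
  ka <- length(ea)
  kb <- length(eb)
  if (ka == 0L && kb == 0L) {
    return(list(value = 1, case = "case2"))
  }
  if (ka == 0L || kb == 0L) {
    return(list(value = 1 / (1 + max(ka, kb)), case = "case3"))
  }
  list(
    value = length(intersect(ea, eb)) / length(union(ea, eb)),
    case = "case4"
  )
}

#' Compare the metabolisms of two organisms
#'
#' Computes the per-pathway local indexes over every reference pathway
#' present in at least one of the two organisms, and the four global
#' indexes:
#' \describe{
#'   \item{psim}{pathway similarity, the arithmetic mean of the per-pathway
#'     functional similarities.}
#'   \item{psim_w}{weighted pathway similarity, the mean of the functional
#'     similarities weighted by \eqn{|R_i \cup R_i'|}; pathways without
#'     reactions carry weight 0, so this index considers reaction pathways
#'     only. \code{NA} (with a warning) when no reaction pathway exists
#'     anywhere.}
#'   \item{ssim}{structure similarity, the arithmetic mean of the
#'     per-pathway structural similarities.}
#'   \item{csim}{combined similarity, the mean of the per-pathway products
#'     \eqn{SimS_i \cdot SimP_i}; being a mean of products of values in
#'     \eqn{[0, 1]} it amplifies differences and never exceeds either
#'     global index it combines.}
#' }
#' The denominator \eqn{n} of all means is the number of pathways present
#' (physical or reaction) in at least one organism; universe pathways absent
#' from both contribute to no sum and no denominator.
#'
#' @inheritParams sim_pathway
#' @return An object of class \code{pairwise_comparison}: a list with
#'   \code{org_a}, \code{org_b}, \code{mode}, \code{n}, the four global
#'   indexes, and \code{rows}, a data frame sorted by pathway number with
#'   columns \code{pathway}, \code{title}, \code{sim_s}, \code{sim_p},
#'   \code{sim_s_case}, \code{sim_p_case}, \code{union_size}.
#' @examples
#' rec <- function(org, num, rx, cpd) {
#'   structure(
#'     list(
#'       org = org, number = num, title = num,
#'       reactions = rx, compounds = cpd
#'     ),
#'     class = "pathway_record"
#'   )
#' }
#' u <- c("00010", "00020")
#' a <- build_network(
#'   list(
#'     "00010" = rec("aaa", "00010", c(R00001 = 1L, R00002 = 1L), "C00022"),
#'     "00020" = rec("aaa", "00020", c(R00002 = 1L), "C00022")
#'   ),
#'   u
#' )
#' compare_pair(a, a)$psim
#' @export
compare_pair <- function(net_a, net_b, mode = c("set", "multiset")) {
  mode <- match.arg(mode)
  check_comparable(net_a, net_b)
  universe <- net_a$universe
  domain <- universe[net_a$status != "absent" | net_b$status != "absent"]
  if (length(domain) == 0L) {
    stop(
      "no pathway of the universe is present in either organism ('",
      net_a$org, "', '", net_b$org, "')",
      call. = FALSE
    )
  }

  rows <- data.frame(
    pathway = domain,
    title = vapply(domain, function(p) {
      if (nzchar(net_a$titles[p])) net_a$titles[[p]] else net_b$titles[[p]]
    }, character(1)),
    sim_s = NA_real_, sim_p = NA_real_,
    sim_s_case = "", sim_p_case = "",
    union_size = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (i in seq_along(domain)) {
    p <- domain[i]
    sp <- sim_pathway(net_a, net_b, p, mode)
    ss <- sim_structure(net_a, net_b, p)
    rows$sim_p[i] <- sp$value
    rows$sim_p_case[i] <- sp$case
    rows$union_size[i] <- sp$union_size
    rows$sim_s[i] <- ss$value
    rows$sim_s_case[i] <- ss$case
  }

  n <- nrow(rows)
  total_union <- sum(rows$union_size)
  psim_w <- if (total_union > 0) {
    sum(rows$sim_p * rows$union_size) / total_union
  } else {
    warning(
      "no reaction pathway in either organism: the weighted pathway ",
      "similarity is undefined (NA)",
      call. = FALSE
    )
    NA_real_
  }

  structure(
    list(
      org_a = net_a$org, org_b = net_b$org, mode = mode, n = n,
      psim = sum(rows$sim_p) / n,
      psim_w = psim_w,
      ssim = sum(rows$sim_s) / n,
      csim = sum(rows$sim_s * rows$sim_p) / n,
      rows = rows
    ),
    class = "pairwise_comparison"
  )
}

#' @export
print.pairwise_comparison <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Metabolism comparison %s vs %s (%s mode, n = %d pathways present)\n",
    x$org_a, x$org_b, x$mode, x$n
  ))
  vals <- c(psim = x$psim, psim_w = x$psim_w, ssim = x$ssim, csim = x$csim)
  for (k in names(vals)) {
    cat(sprintf(
      "  %-7s %s\n", k,
      if (is.na(vals[k])) "NA (no reaction pathways)" else {
        sprintf("%.*f  (%.2f%%)", digits, vals[k], 100 * vals[k])
      }
    ))
  }
  invisible(x)
}

#' @export
summary.pairwise_comparison <- function(object, ...) {
  print(object, ...)
  cat("\nLocal index cases:\n")
  print(table(
    functional = object$rows$sim_p_case,
    structural = object$rows$sim_s_case
  ))
  invisible(object)
}
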