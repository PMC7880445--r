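#' Parse a KGML pathway file
#'
#' Reads one KGML (KEGG Markup Language) document and extracts the content
#' needed for the two-level metabolism representation: the multiset of
#' reaction accessions (R-numbers) and the set of compound accessions
#' (C-numbers) declared as compound-type entries.
#'
#' A reaction declaration whose \code{name} attribute lists several
#' space-separated R-numbers contributes one count increment per listed
#' accession, so a name repeated within one declaration is counted with its
#' multiplicity. Compounds are taken from \code{entry} elements with
#' \code{type="compound"}; reaction substrate/product sub-elements are not
#' consulted, matching the map-level compound inventory KEGG draws on a
#' pathway image. Maplink relations are recognised and discarded, and
#' reaction direction attributes are ignored: reaction identity is the
#' R-number alone.
#'
#' @param x KGML content: a literal XML string, a file path, or anything
#'   accepted by [xml2::read_xml()].
#' @param source optional label (normally the file name) used in error
#'   messages.
#' @return An object of class \code{pathway_record}: a list with elements
#'   \code{org} (organism code), \code{number} (5-digit reference-pathway
#'   number), \code{title} (display name, \code{""} if absent),
#'   \code{reactions} (named integer vector, accession to count; empty for
#'   a physical pathway) and \code{compounds} (character vector of distinct
#'   C-numbers, unfiltered).
#' @examples
#' xml <- paste0(
#'   '<pathway org="eco" number="00010" title="Glycolysis">',
#'   '<entry id="1" name="cpd:C00022" type="compound"/>',
#'   '<reaction id="2" name="rn:R00200" type="reversible"/>',
#'   "</pathway>"
#' )
#' rec <- parse_kgml(xml)
#' rec$reactions
#' @export
parse_kgml <- function(x, source = NULL) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) {
      stop(
        "malformed KGML", if (!is.null(source)) paste0(" in '", source, "'"),
        ": ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "pathway") {
    stop(
      "not a KGML document", if (!is.null(source)) paste0(" ('", source, "')"),
      ": root element is <", xml2::xml_name(root), ">, expected <pathway>",
      call. = FALSE
    )
  }
  org <- xml2::xml_attr(root, "org")
  number <- xml2::xml_attr(root, "number")
  if (is.na(org) || is.na(number)) {
    stop(
      "KGML validation error",
      if (!is.null(source)) paste0(" in '", source, "'"),
      ": the <pathway> root must carry 'org' and 'number' attributes",
      call. = FALSE
    )
  }
  title <- xml2::xml_attr(root, "title")
  if (is.na(title)) title <- ""

  ## reaction multiset: one increment per accession occurrence across all
  ## reaction declarations
  rx_names <- xml2::xml_attr(xml2::xml_find_all(doc, ".//reaction"), "name")
  rx_tokens <- strip_accessions(rx_names, "rn", "^R[0-9]{5}$")
  reactions <- as_multiset(rx_tokens)

  cpd_names <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//entry[@type='compound']"), "name"
  )
  compounds <- sort(unique(strip_accessions(cpd_names, "cpd", "^C[0-9]{5}$")))

  structure(
    list(
      org = org, number = number, title = title,
      reactions = reactions, compounds = compounds
    ),
    class = "pathway_record"
  )
}

## split whitespace-separated accession fields, strip a "db:" prefix, keep
## tokens matching the accession pattern (glycans, drug ids etc. are dropped)
strip_accessions <- function(fields, prefix, pattern) {
  fields <- fields[!is.na(fields)]
  if (length(fields) == 0L) return(character(0))
  tokens <- unlist(strsplit(fields, "[[:space:]]+"), use.names = FALSE)
  tokens <- tokens[nzchar(tokens)]
  tokens <- sub(paste0("^", prefix, ":"), "", tokens)
  tokens[grepl(pattern, tokens)]
}

## named integer vector, sorted by accession
as_multiset <- function(tokens) {
  if (length(tokens) == 0L) {
    return(structure(integer(0), names = character(0)))
  }
  tab <- table(tokens)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(names(counts))]
}

#' @export
print.pathway_record <- function(x, ...) {
  kind <- if (length(x$reactions) == 0L) "physical" else "reaction"
  cat(
    sprintf(
      "KGML pathway record %s%s '%s' (%s pathway)\n",
      x$org, x$number, x$title, kind
    ),
    sprintf(
      "  reactions: %d accessions, %d occurrences; compounds: %d\n",
      length(x$reactions), sum(x$reactions), length(x$compounds)
    )
  )
  invisible(x)
}

#' Load all cached KGML files of one organism over a pathway universe
#'
#' Scans a directory of KGML files named \code{<org><number>.xml} and parses
#' the ones whose 5-digit pathway number belongs to \code{universe}. Every
#' universe number is represented in the result: either by a parsed
#' \code{pathway_record} or by \code{NULL}, the explicit marker that no KGML
#' file exists for that organism-pathway (the pathway is absent from the
#' organism's metabolism).
#'
#' @param dir directory containing KGML files.
#' @param universe character vector of 5-digit reference-pathway numbers.
#' @param org optional organism code; when given, only files starting with
#'   that code are considered and parsed records are checked against it.
#' @return A named list over \code{universe} (ascending): each element a
#'   \code{pathway_record} or \code{NULL} (absent).
#' @export
load_organism <- function(dir, universe, org = NULL) {
  universe <- check_universe(universe)
  if (!dir.exists(dir)) stop("no such directory: '", dir, "'", call. = FALSE)
  files <- list.files(dir, pattern = "\\.xml$")
  if (!is.null(org)) files <- files[startsWith(files, org)]

  out <- stats::setNames(vector("list", length(universe)), universe)
  seen <- character(0)
  for (i in seq_along(files)) {
    num <- regmatches(files[i], regexpr("[0-9]{5}(?=\\.xml$)", files[i], perl = TRUE))
    if (length(num) == 0L) {
      warning(
        "skipping '", files[i], "': no 5-digit pathway number in the filename",
        call. = FALSE
      )
      next
    }
    if (!num %in% universe) {
      warning(
        "skipping '", files[i], "': pathway ", num,
        " is not in the configured universe",
        call. = FALSE
      )
      next
    }
    if (num %in% seen) {
      stop(
        "duplicate KGML files for pathway ", num, " in '", dir, "'",
        call. = FALSE
      )
    }
    seen <- c(seen, num)
    path <- file.path(dir, files[i])
    rec <- parse_kgml(path, source = files[i])
    if (!is.null(org) && rec$org != org) {
      warning(
        "'", files[i], "' declares org '", rec$org, "', expected '", org, "'",
        call. = FALSE
      )
    }
    if (rec$number != num) {
      warning(
        "'", files[i], "' declares pathway number ", rec$number,
        ", filename says ", num, "; using the filename",
        call. = FALSE
      )
      rec$number <- num
    }
    out[[num]] <- rec
  }
  out
}

#' Default ubiquitous-compound exclusion list
#'
#' Near-universal metabolites excluded from the shared-compound edge rule so
#' that they do not connect essentially every pathway to every other: water
#' (C00001), ATP (C00002), ADP (C00008) and phosphate (C00009). The list is
#' a default, not a constant: pass any character vector of C-numbers as the
#' \code{ubiquitous} argument of [build_network()] to override it.
#'
#' @return character vector of compound accessions.
#' @export
default_ubiquitous <- function() {
  c("C00001", "C00002", "C00008", "C00009")
}

## shared validation: non-empty duplicate-free 5-digit numbers, returned in
## the fixed ascending order that position-aligns matrices across organisms
check_universe <- function(universe) {
  universe <- as.character(universe)
  if (length(universe) == 0L) stop("the pathway universe is empty", call. = FALSE)
  if (anyDuplicated(universe)) {
    stop("duplicate pathway numbers in the universe", call. = FALSE)
  }
  bad <- universe[!grepl("^[0-9]{5}$", universe)]
  if (length(bad)) {
    stop(
      "invalid pathway numbers (need 5 digits): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  sort(universe)
}
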