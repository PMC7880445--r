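## Optional live retrieval from the KEGG REST service. Every downstream
## module consumes only the on-disk cache, so the client is never needed to
## run a comparison, and the test suite exercises it exclusively through an
## injected transport.

kegg_base_url <- "https://rest.kegg.jp"

#' Default HTTP transport for the KEGG REST client
#'
#' A transport is a function taking a URL and returning
#' \code{list(status = <integer>, body = <character scalar>)}. The default
#' uses base R connections; any failure to read is reported as status 404
#' with an empty body (KEGG signals "no such pathway" that way). Tests and
#' offline pipelines inject their own transport instead.
#'
#' @return a transport function.
#' @export
kegg_transport <- function() {
  function(url) {
    body <- tryCatch(
      paste(suppressWarnings(readLines(url)), collapse = "\n"),
      error = function(e) NULL
    )
    if (is.null(body)) {
      list(status = 404L, body = "")
    } else {
      list(status = 200L, body = body)
    }
  }
}

#' Download (or reuse) the list of KEGG organisms
#'
#' Retrieves the organism list from the KEGG REST service and caches it as a
#' TSV under \code{cache_dir}, so later runs work offline. Each entry has a
#' unique organism code, a species name and a taxonomic lineage.
#'
#' @param cache_dir directory for the cached list.
#' @param transport HTTP transport (see [kegg_transport()]).
#' @param offline if \code{TRUE}, only the cache is consulted.
#' @param refresh if \code{TRUE}, re-download even when a cache exists.
#' @param retries number of attempts before giving up.
#' @return data frame with columns \code{code}, \code{name}, \code{lineage}.
#' @export
fetch_organism_list <- function(cache_dir, transport = kegg_transport(),
                                offline = FALSE, refresh = FALSE,
                                retries = 3L) {
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  cache <- file.path(cache_dir, "organism.tsv")

  if ((offline || file.exists(cache)) && !refresh) {
    if (!file.exists(cache)) {
      stop("offline mode but no cached organism list at '", cache, "'",
        call. = FALSE
      )
    }
    return(parse_organism_list(readLines(cache, warn = FALSE), cache))
  }

  url <- paste0(kegg_base_url, "/list/organism")
  body <- NULL
  for (attempt in seq_len(retries)) {
    res <- transport(url)
    if (res$status == 200L && nzchar(res$body)) {
      body <- res$body
      break
    }
  }
  if (is.null(body)) {
    stop(
      "could not retrieve the KEGG organism list after ", retries,
      " attempts",
      call. = FALSE
    )
  }
  lines <- strsplit(body, "\n", fixed = TRUE)[[1]]
  out <- parse_organism_list(lines, url)
  writeLines(lines, cache)
  out
}

## KEGG list/organism rows: T-number <tab> code <tab> name <tab> lineage
parse_organism_list <- function(lines, source) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty organism list from '", source, "'", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    stop(
      "malformed organism list from '", source,
      "': expected 4 tab-separated columns",
      call. = FALSE
    )
  }
  out <- data.frame(
    code = vapply(fields, `[`, character(1), 2L),
    name = vapply(fields, `[`, character(1), 3L),
    lineage = vapply(fields, `[`, character(1), 4L),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$code)) {
    stop("malformed organism list from '", source, "': duplicate codes",
      call. = FALSE
    )
  }
  out
}

#' Fetch and cache the KGML files of one organism
#'
#' For every reference pathway of the universe, downloads the organism's
#' KGML to \code{<cache_dir>/<code>/<code><number>.xml}, or records an
#' \code{<code><number>.absent} marker when the service has no such pathway
#' for the organism (an absent pathway is a normal outcome, cached so that
#' re-runs are idempotent and offline-replayable). Transport failures are
#' collected and raised at the end, listing the affected pathway numbers.
#' Requests are serialized with an inter-request delay.
#'
#' @param code organism code.
#' @param universe character vector of 5-digit pathway numbers.
#' @param cache_dir cache root.
#' @param transport HTTP transport (see [kegg_transport()]).
#' @param organisms optional organism table (from [fetch_organism_list()]);
#'   when given, \code{code} is validated against it before any request.
#' @param refresh if \code{TRUE}, ignore cached files and re-fetch.
#' @param delay seconds between consecutive live requests (politeness).
#' @return named character vector over the universe: \code{"present"} or
#'   \code{"absent"}.
#' @export
sync_organism <- function(code, universe, cache_dir,
                          transport = kegg_transport(), organisms = NULL,
                          refresh = FALSE, delay = 0.35) {
  universe <- check_universe(universe)
  if (!is.null(organisms) && !code %in% organisms$code) {
    stop("unknown organism code '", code, "'", call. = FALSE)
  }
  org_dir <- file.path(cache_dir, code)
  dir.create(org_dir, recursive = TRUE, showWarnings = FALSE)

  status <- stats::setNames(rep(NA_character_, length(universe)), universe)
  failed <- character(0)
  first_request <- TRUE
  for (num in universe) {
    xml_path <- file.path(org_dir, paste0(code, num, ".xml"))
    absent_path <- file.path(org_dir, paste0(code, num, ".absent"))
    if (!refresh && file.exists(xml_path)) {
      status[num] <- "present"
      next
    }
    if (!refresh && file.exists(absent_path)) {
      status[num] <- "absent"
      next
    }
    if (!first_request && delay > 0) Sys.sleep(delay)
    first_request <- FALSE
    res <- transport(paste0(kegg_base_url, "/get/", code, num, "/kgml"))
    if (res$status == 200L && nzchar(res$body)) {
      writeLines(res$body, xml_path)
      status[num] <- "present"
    } else if (res$status %in% c(200L, 404L)) {
      ## not-found or empty body: the organism lacks this pathway
      writeLines(
        paste0("no KGML for ", code, num, " at sync time"), absent_path
      )
      status[num] <- "absent"
    } else {
      failed <- c(failed, num)
    }
  }
  if (length(failed)) {
    stop(
      "partial sync for '", code, "': transport failed for pathways ",
      paste(failed, collapse = ", "),
      call. = FALSE
    )
  }
  status
}
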