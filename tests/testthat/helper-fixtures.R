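# Shared helpers: hand-built records/networks small enough to verify by eye.

make_record <- function(org, number, reactions = integer(0),
                        compounds = character(0), title = number) {
  rx <- if (length(reactions) == 0L) {
    structure(integer(0), names = character(0))
  } else {
    keggsim:::as_multiset(rep(names(reactions), reactions))
  }
  structure(
    list(
      org = org, number = number, title = title,
      reactions = rx, compounds = sort(unique(compounds))
    ),
    class = "pathway_record"
  )
}

# records: named list number -> list(reactions=, compounds=) or NULL (absent)
make_net <- function(org, universe, entries,
                     ubiquitous = default_ubiquitous()) {
  records <- stats::setNames(vector("list", length(universe)), universe)
  for (num in names(entries)) {
    e <- entries[[num]]
    if (is.null(e)) next
    records[[num]] <- make_record(
      org, num,
      reactions = e$reactions %||% integer(0),
      compounds = e$compounds %||% character(0)
    )
  }
  build_network(records, universe, ubiquitous = ubiquitous, org = org)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rx <- function(...) {
  v <- c(...)
  stats::setNames(as.integer(v), names(v))
}

kgml_wrap <- function(inner, org = "eco", number = "00010",
                      title = "Test pathway", attrs = TRUE) {
  root <- if (attrs) {
    sprintf(
      '<pathway name="path:%s%s" org="%s" number="%s" title="%s">',
      org, number, org, number, title
    )
  } else {
    "<pathway>"
  }
  paste0(
    '<?xml version="1.0"?>', root, paste(inner, collapse = ""), "</pathway>"
  )
}
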