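## Synthetic-data module: seeded generation of organism groups as KGML files
## with controlled pathway presence, reaction overlap, multiplicities and
## compound sharing, plus an independent brute-force oracle for every
## similarity index. Generated accessions use the reserved high ranges
## (C9xxxx, R9xxxx, pathway numbers 9xxxx) so synthetic files can never
## collide with real KEGG identifiers in a mixed cache.

#' Construct a fixture specification
#'
#' A fixture spec fully determines a synthetic group of organisms: for every
#' (organism, reference pathway) it fixes absence, or the exact reaction
#' multiset (empty for a physical pathway) and compound set. Given the spec,
#' the emitted KGML bytes are deterministic.
#'
#' @param universe character vector of 5-digit pathway numbers.
#' @param plan named list (one element per organism code); each element a
#'   named list over pathway numbers whose entries are \code{NULL} (absent)
#'   or \code{list(reactions = <named integer counts>, compounds =
#'   <character>, title = <string, optional>)}.
#' @param seed integer recorded in the spec (provenance; the plan itself is
#'   already fully explicit).
#' @return an object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(universe, plan, seed = NA_integer_) {
  universe <- check_universe(universe)
  if (is.null(names(plan)) || any(!nzchar(names(plan)))) {
    stop("the plan must be a named list, one element per organism code",
      call. = FALSE
    )
  }
  for (org in names(plan)) {
    entries <- plan[[org]]
    extra <- setdiff(names(entries), universe)
    if (length(extra)) {
      stop(
        "plan for '", org, "' names pathways outside the universe: ",
        paste(extra, collapse = ", "),
        call. = FALSE
      )
    }
    norm <- stats::setNames(vector("list", length(universe)), universe)
    for (num in names(entries)) {
      e <- entries[[num]]
      if (is.null(e)) next
      if (is.null(e$reactions)) {
        e$reactions <- structure(integer(0), names = character(0))
      }
      rx <- e$reactions
      if (length(rx) > 0L && (is.null(names(rx)) || any(rx < 1L))) {
        stop(
          "plan for '", org, "' pathway ", num,
          ": reactions must be a named vector of counts >= 1",
          call. = FALSE
        )
      }
      e$reactions <- as_multiset(rep(names(rx), rx))
      e$compounds <- sort(unique(as.character(e$compounds)))
      if (is.null(e$title)) e$title <- paste0("Synthetic pathway ", num)
      norm[[num]] <- e
    }
    plan[[org]] <- norm
  }
  structure(
    list(
      seed = seed, universe = universe,
      organisms = names(plan), plan = plan
    ),
    class = "fixture_spec"
  )
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf(
    "Fixture spec: %d organisms x %d pathways (seed %s)\n",
    length(x$organisms), length(x$universe), format(x$seed)
  ))
  invisible(x)
}

## run `expr` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Generate a random fixture specification
#'
#' Draws a reproducible synthetic organism group. Each pathway owns a base
#' pool of reaction accessions from which every organism samples (the
#' \code{reaction_overlap} retention probability controls how much two
#' organisms' realisations of the same pathway overlap), plus a few private
#' reactions; multiplicities above 1 arise with probability
#' \code{p_duplicate}. Compound sharing is planted per pathway pair: a pair
#' selected with probability \code{shared_compound_rate} receives a
#' dedicated linking compound in the organisms that realise it, and
#' ubiquitous decoys (water, ATP, ADP, phosphate) are sprinkled into
#' compound sets so that downstream filtering is actually exercised.
#'
#' @param seed integer seed; the same seed always yields the same spec.
#' @param n_organisms number of organisms (codes \code{zaa}, \code{zab}, ...).
#' @param n_pathways size of the pathway universe (numbers \code{9xxxx}).
#' @param max_reactions largest base reaction pool per pathway.
#' @param p_absent,p_physical per-(organism, pathway) probabilities of the
#'   absent and physical states; the rest are reaction pathways.
#' @param reaction_overlap probability that an organism retains a base-pool
#'   reaction in its realisation of a pathway.
#' @param p_duplicate probability that a retained reaction appears with
#'   multiplicity 2 (exercises multiset mode).
#' @param shared_compound_rate probability that a pathway pair is planted
#'   with a shared linking compound.
#' @param p_decoy probability that a pathway's compound set also contains a
#'   ubiquitous decoy.
#' @return a \code{fixture_spec}.
#' @export
random_fixture_spec <- function(seed, n_organisms = 2, n_pathways = 6,
                                max_reactions = 12, p_absent = 0.15,
                                p_physical = 0.15, reaction_overlap = 0.6,
                                p_duplicate = 0.25,
                                shared_compound_rate = 0.5, p_decoy = 0.5) {
  stopifnot(n_organisms >= 2, n_pathways >= 1, max_reactions >= 1)
  with_seed(seed, {
    universe <- paste0("9", sprintf("%04d", seq_len(n_pathways)))
    organisms <- vapply(seq_len(n_organisms), function(i) {
      paste0("z", letters[(i - 1L) %/% 26L + 1L], letters[(i - 1L) %% 26L + 1L])
    }, character(1))

    ## disjoint base reaction pools per pathway
    sizes <- seq.int(2L, max(2L, max_reactions))
    pool_sizes <- sizes[sample.int(length(sizes), n_pathways, replace = TRUE)]
    offsets <- cumsum(c(0L, pool_sizes[-n_pathways]))
    pools <- lapply(seq_len(n_pathways), function(i) {
      sprintf("R9%04d", offsets[i] + seq_len(pool_sizes[i]))
    })

    ## planted pairwise linking compounds, one accession per pathway pair
    pair_share <- matrix(FALSE, n_pathways, n_pathways)
    link_cpd <- matrix("", n_pathways, n_pathways)
    k <- 0L
    if (n_pathways > 1L) {
      for (i in seq_len(n_pathways - 1L)) {
        for (j in seq.int(i + 1L, n_pathways)) {
          k <- k + 1L
          pair_share[i, j] <- stats::runif(1) < shared_compound_rate
          link_cpd[i, j] <- sprintf("C9%04d", k)
        }
      }
    }
    private_cpd_base <- k

    plan <- stats::setNames(vector("list", n_organisms), organisms)
    private_rx <- 0L
    private_cpd <- private_cpd_base
    for (o in seq_len(n_organisms)) {
      entries <- stats::setNames(vector("list", n_pathways), universe)
      roll <- stats::runif(n_pathways)
      status <- ifelse(
        roll < p_absent, "absent",
        ifelse(roll < p_absent + p_physical, "physical", "reaction")
      )
      ## an empty metabolism breaks the comparison domain; force one node
      if (all(status == "absent")) status[1L] <- "reaction"
      for (i in seq_len(n_pathways)) {
        if (status[i] == "absent") next
        reactions <- structure(integer(0), names = character(0))
        if (status[i] == "reaction") {
          keep <- pools[[i]][stats::runif(pool_sizes[i]) < reaction_overlap]
          n_private <- stats::rbinom(1L, 2L, 0.5)
          if (n_private > 0L) {
            keep <- c(keep, sprintf("R8%04d", private_rx + seq_len(n_private)))
            private_rx <- private_rx + n_private
          }
          if (length(keep) == 0L) keep <- pools[[i]][1L]
          counts <- 1L + stats::rbinom(length(keep), 1L, p_duplicate)
          reactions <- as_multiset(rep(keep, counts))
        }
        compounds <- character(0)
        if (n_pathways > 1L) {
          for (j in seq_len(n_pathways)) {
            a <- min(i, j)
            b <- max(i, j)
            if (a == b || !pair_share[a, b]) next
            if (status[j] != "absent" && stats::runif(1) < 0.85) {
              compounds <- c(compounds, link_cpd[a, b])
            }
          }
        }
        n_private_c <- 1L + stats::rbinom(1L, 3L, 0.4)
        compounds <- c(
          compounds, sprintf("C8%04d", private_cpd + seq_len(n_private_c))
        )
        private_cpd <- private_cpd + n_private_c
        if (stats::runif(1) < p_decoy) {
          compounds <- c(compounds, sample(default_ubiquitous(), 1L))
        }
        entries[[universe[i]]] <- list(
          reactions = reactions,
          compounds = sort(unique(compounds)),
          title = paste0("Synthetic pathway ", universe[i])
        )
      }
      plan[[organisms[o]]] <- entries
    }
    fixture_spec(universe, plan, seed = seed)
  })
}

## deterministic KGML text for one (organism, pathway) plan entry
kgml_text <- function(org, num, entry) {
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(
      '<pathway name="path:%s%s" org="%s" number="%s" title="%s">',
      org, num, org, num, entry$title
    )
  )
  id <- 0L
  for (cpd in entry$compounds) {
    id <- id + 1L
    lines <- c(lines, sprintf(
      '  <entry id="%d" name="cpd:%s" type="compound"/>', id, cpd
    ))
  }
  ## a map-type entry and a maplink relation: downstream parsing must skip
  ## both without effect
  id <- id + 1L
  lines <- c(lines, sprintf(
    '  <entry id="%d" name="path:%s00000" type="map"/>', id, org
  ))
  if (id >= 2L) {
    lines <- c(lines, sprintf(
      '  <relation entry1="1" entry2="%d" type="maplink"><subtype name="compound" value="1"/></relation>',
      id
    ))
  }
  for (acc in names(entry$reactions)) {
    id <- id + 1L
    lines <- c(lines, sprintf(
      '  <reaction id="%d" name="%s" type="reversible"/>',
      id, paste(rep(paste0("rn:", acc), entry$reactions[[acc]]), collapse = " ")
    ))
  }
  c(lines, "</pathway>")
}

#' Materialise a fixture spec as KGML files
#'
#' Writes one KGML file per (organism, present pathway) to
#' \code{<out_dir>/<org>/<org><number>.xml}, together with a config-style
#' manifest echoing the plan. Output bytes depend only on the spec, so the
#' same spec (hence the same seed) always produces identical files.
#'
#' @param spec a \code{fixture_spec}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the character vector of files written.
#' @export
generate_kgml_fixtures <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  manifest <- c(
    paste0("seed = ", spec$seed),
    paste0("universe = ", paste(spec$universe, collapse = ",")),
    paste0("organisms = ", paste(spec$organisms, collapse = ","))
  )
  for (org in spec$organisms) {
    org_dir <- file.path(out_dir, org)
    dir.create(org_dir, showWarnings = FALSE)
    for (num in spec$universe) {
      entry <- spec$plan[[org]][[num]]
      key <- paste0(org, ".", num)
      if (is.null(entry)) {
        manifest <- c(manifest, paste0(key, ".status = absent"))
        next
      }
      manifest <- c(
        manifest,
        paste0(
          key, ".status = ",
          if (length(entry$reactions) == 0L) "physical" else "reaction"
        ),
        paste0(
          key, ".reactions = ",
          paste(
            sprintf("%s:%d", names(entry$reactions), entry$reactions),
            collapse = ";"
          )
        ),
        paste0(key, ".compounds = ", paste(entry$compounds, collapse = ";"))
      )
      path <- file.path(org_dir, paste0(org, num, ".xml"))
      writeLines(kgml_text(org, num, entry), path)
      written <- c(written, path)
    }
  }
  manifest_path <- file.path(out_dir, "manifest.ini")
  writeLines(manifest, manifest_path)
  invisible(c(written, manifest_path))
}

#' Run the full reconstruction pipeline on a fixture spec
#'
#' Convenience wrapper used throughout the tests: generates the KGML files,
#' loads each organism back through the parser and builds its two-level
#' network — the exact path real KEGG data takes.
#'
#' @param spec a \code{fixture_spec}.
#' @param dir directory for the generated files (a fresh temporary directory
#'   by default).
#' @param ubiquitous exclusion list passed to [build_network()].
#' @return named list of \code{two_level_network}s, one per organism.
#' @export
fixture_networks <- function(spec, dir = tempfile("kgmlfix"),
                             ubiquitous = default_ubiquitous()) {
  generate_kgml_fixtures(spec, dir)
  nets <- lapply(spec$organisms, function(org) {
    records <- load_organism(file.path(dir, org), spec$universe, org = org)
    build_network(records, spec$universe, ubiquitous = ubiquitous, org = org)
  })
  stats::setNames(nets, spec$organisms)
}

## ---- independent brute-force oracle ---------------------------------------
## Works directly on the spec's plan, never touching KGML, networks or the
## similarity module. Multisets are expanded to vectors with repetitions and
## intersected by explicit one-by-one matching.

oracle_expand <- function(rx, mode) {
  v <- rep(names(rx), rx)
  if (mode == "set") unique(v) else v
}

oracle_inter_card <- function(a, b) {
  inter <- 0L
  for (x in a) {
    hit <- match(x, b)
    if (!is.na(hit)) {
      inter <- inter + 1L
      b <- b[-hit]
    }
  }
  inter
}

#' Brute-force oracle for the similarity indexes of a fixture pair
#'
#' Recomputes every local and global similarity index for two organisms of a
#' fixture spec by direct enumeration of the planned reaction collections
#' and compound sets, as an implementation independent of the KGML/network/
#' similarity pipeline. Used to validate the pipeline end to end.
#'
#' @param spec a \code{fixture_spec}.
#' @param mode \code{"set"} or \code{"multiset"}.
#' @param pair two organism codes from the spec (the first two by default).
#' @param ubiquitous compound exclusion list.
#' @return list with \code{rows} (data frame: \code{pathway}, \code{sim_s},
#'   \code{sim_p}, \code{union_size}) and \code{psim}, \code{psim_w},
#'   \code{ssim}, \code{csim}, \code{n}.
#' @export
fixture_oracle <- function(spec, mode = c("set", "multiset"),
                           pair = spec$organisms[1:2],
                           ubiquitous = default_ubiquitous()) {
  stopifnot(inherits(spec, "fixture_spec"), length(pair) == 2L)
  mode <- match.arg(mode)
  universe <- spec$universe

  side <- function(org) {
    entries <- spec$plan[[org]]
    present <- universe[!vapply(entries, is.null, logical(1))]
    filtered <- lapply(entries, function(e) {
      if (is.null(e)) character(0) else setdiff(e$compounds, ubiquitous)
    })
    neighbours <- stats::setNames(
      lapply(universe, function(p) character(0)), universe
    )
    for (p in present) {
      for (q in present) {
        if (q == p) next
        if (length(intersect(filtered[[p]], filtered[[q]])) > 0L) {
          neighbours[[p]] <- c(neighbours[[p]], q)
        }
      }
    }
    list(entries = entries, present = present, neighbours = neighbours)
  }
  a <- side(pair[1])
  b <- side(pair[2])

  domain <- universe[universe %in% a$present | universe %in% b$present]
  rows <- data.frame(
    pathway = domain, sim_s = NA_real_, sim_p = NA_real_,
    union_size = NA_real_, stringsAsFactors = FALSE
  )
  for (i in seq_along(domain)) {
    p <- domain[i]
    in_a <- p %in% a$present
    in_b <- p %in% b$present
    if (!in_a || !in_b) {
      present_side <- if (in_a) a else b
      rows$sim_p[i] <- 0
      rows$sim_s[i] <- 0
      rows$union_size[i] <- length(
        oracle_expand(present_side$entries[[p]]$reactions, mode)
      )
      next
    }
    ra <- oracle_expand(a$entries[[p]]$reactions, mode)
    rb <- oracle_expand(b$entries[[p]]$reactions, mode)
    if (length(ra) == 0L && length(rb) == 0L) {
      rows$sim_p[i] <- 1
      rows$union_size[i] <- 0
    } else {
      inter <- oracle_inter_card(ra, rb)
      uni <- length(ra) + length(rb) - inter
      rows$sim_p[i] <- if (length(ra) == 0L || length(rb) == 0L) 0 else inter / uni
      rows$union_size[i] <- uni
    }
    na <- a$neighbours[[p]]
    nb <- b$neighbours[[p]]
    if (length(na) == 0L && length(nb) == 0L) {
      rows$sim_s[i] <- 1
    } else if (length(na) == 0L || length(nb) == 0L) {
      rows$sim_s[i] <- 1 / (1 + max(length(na), length(nb)))
    } else {
      rows$sim_s[i] <- length(intersect(na, nb)) / length(union(na, nb))
    }
  }

  n <- nrow(rows)
  total_union <- sum(rows$union_size)
  list(
    rows = rows,
    psim = sum(rows$sim_p) / n,
    psim_w = if (total_union > 0) {
      sum(rows$sim_p * rows$union_size) / total_union
    } else {
      NA_real_
    },
    ssim = sum(rows$sim_s) / n,
    csim = sum(rows$sim_s * rows$sim_p) / n,
    n = n
  )
}

#' Planted two-block similarity matrix
#'
#' Builds a synthetic organisms-by-organisms similarity matrix with a known
#' group structure: within-block similarities are drawn uniformly from
#' \code{within} and between-block similarities from \code{between}. Used to
#' validate that complete-linkage clustering recovers planted groups.
#'
#' @param seed integer seed.
#' @param block_sizes integer vector of block sizes (organism codes are
#'   generated as \code{g<block><letter>}).
#' @param within,between length-2 ranges for within- and between-block
#'   similarities.
#' @param index,mode labels for the resulting matrix.
#' @return list with \code{matrix} (a \code{similarity_matrix}) and
#'   \code{blocks} (named integer vector: organism to block id).
#' @export
planted_similarity_matrix <- function(seed, block_sizes = c(4, 4),
                                      within = c(0.8, 1), between = c(0, 0.3),
                                      index = "psim", mode = "set") {
  stopifnot(length(block_sizes) >= 2, all(block_sizes >= 1))
  with_seed(seed, {
    blocks <- rep(seq_along(block_sizes), block_sizes)
    n <- length(blocks)
    orgs <- paste0("g", blocks, letters[unlist(lapply(block_sizes, seq_len))])
    values <- matrix(1, n, n, dimnames = list(orgs, orgs))
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        rng <- if (blocks[i] == blocks[j]) within else between
        values[i, j] <- values[j, i] <- stats::runif(1, rng[1], rng[2])
      }
    }
    list(
      matrix = as_similarity_matrix(values, index = index, mode = mode),
      blocks = stats::setNames(blocks, orgs)
    )
  })
}
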