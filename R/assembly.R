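#' One-pot Golden Gate assembly
#'
#' The reaction is modelled as an enumeration, not a stochastic simulation:
#' all parts are digested, a directed graph is built whose nodes are
#' oriented fragments and whose edges are compatible sticky-end pairs, and
#' every simple cycle up to a size bound becomes a candidate circular
#' product.  Correct junctions lose the recognition site, so only the
#' intended products are stable (not re-cleavable); re-ligated entry
#' vectors recreate their sites and stay substrates.  This matches the
#' selection logic of the screening-based workflow without modelling
#' kinetics or concentrations.
#'
#' @name assembly
NULL

oriented_ends <- function(frag, orient) {
  if (orient == "+") list(left = frag$left_end, right = frag$right_end)
  else list(left = frag$right_end, right = frag$left_end)
}

#' Enumerate circular products from a set of fragments
#'
#' Each physical fragment is used at most once per circle, in either
#' orientation; distinct products are reported once (canonical rotation
#' identity, the two strands counted as one molecule).
#'
#' @param frags list of linear [ds_seq()] fragments.
#' @param max_cycle maximum number of oriented fragments per circle.
#' @return list of circular [ds_seq()] products (with `meta$members`).
#' @export
assemble_fragments <- function(frags, max_cycle = 6L) {
  m <- length(frags)
  if (!m) return(list())
  ends <- list()
  for (i in seq_len(m)) for (o in c("+", "-"))
    ends[[paste0(i, o)]] <- oriented_ends(frags[[i]], o)
  edge_ok <- function(a, b) ends_compatible(ends[[a]]$right, ends[[b]]$left)

  cycles <- list()
  for (leader in seq_len(m)) {
    start <- paste0(leader, "+")
    # DFS over simple paths whose members all have index > leader
    dfs <- function(path, used) {
      cur <- path[length(path)]
      if (edge_ok(cur, start))
        cycles[[length(cycles) + 1L]] <<- path
      if (length(path) >= max_cycle) return(invisible())
      for (j in seq_len(m)) {
        if (j <= leader || used[j]) next
        for (o in c("+", "-")) {
          nxt <- paste0(j, o)
          if (edge_ok(cur, nxt)) {
            used[j] <- TRUE
            dfs(c(path, nxt), used)
            used[j] <- FALSE
          }
        }
      }
    }
    used <- rep(FALSE, m); used[leader] <- TRUE
    dfs(start, used)
  }

  products <- list(); seen <- character()
  for (cy in cycles) {
    idx <- as.integer(sub("[+-]$", "", cy))
    ori <- sub("^[0-9]+", "", cy)
    fs <- lapply(seq_along(idx), function(k) {
      f <- frags[[idx[k]]]
      if (ori[k] == "-") ds_revcomp(f) else f
    })
    joined <- Reduce(ligate_fragments, fs)
    circ <- circularize(joined)
    key <- ds_canonical(circ)
    if (key %in% seen) next
    seen <- c(seen, key)
    circ$meta$cycle <- cy
    products[[length(products) + 1L]] <- circ
  }
  products
}

classify_product <- function(circ, parts) {
  members <- circ$meta$members
  ids <- vapply(members, function(mm) mm$id %||% NA_character_, character(1))
  part_ids <- vapply(parts, function(p) p$id %||% NA_character_, character(1))
  roles <- vapply(parts, function(p) p$role %||% NA_character_, character(1))
  dest_id <- part_ids[match("destination", roles)]

  if (length(unique(ids)) == 1L && !is.na(ids[1])) {
    src <- parts[[match(ids[1], part_ids)]]
    if (!is.na(src$topology) && src$topology == "circular" &&
        ds_canonical(circ) == ds_canonical(src)) {
      if (!is.na(dest_id) && ids[1] == dest_id) return("recircularized_destination")
      return("re_ligated_entry")
    }
  }
  role_of <- function(id) roles[match(id, part_ids)]
  member_roles <- vapply(ids, role_of, character(1))
  if (!is.na(dest_id) &&
      length(members) == 4L &&
      setequal(member_roles, c("up", "down", "cargo_resistance", "destination")) &&
      !anyDuplicated(member_roles) &&
      has_feature(circ, "bla") &&
      all(c("up", "cargo", "bsu_marker", "down") %in% circ$features$label))
    return("final_vector")
  "other_byproduct"
}

#' Predict colony screening color for a product
#'
#' An intact mRFP1 stuffer reports red (unchanged destination vector); an
#' intact mkate2 cargo reports light red; an intact lacZ-alpha fragment
#' (including the premature-stop variants) reports blue on X-Gal; anything
#' else is white.  Unknown reporters fall through to white with a note.
#'
#' @param product circular [ds_seq()] or `assembly_product`.
#' @param xgal is X-Gal present in the plate?
#' @return one of `"red"`, `"light_red"`, `"blue"`, `"white"`.
#' @export
predict_color <- function(product, xgal = FALSE) {
  seq <- if (inherits(product, "assembly_product")) product$sequence else product
  labs <- seq$features$label
  if ("mRFP1" %in% labs) return("red")
  if ("mkate2" %in% labs) return("light_red")
  if (any(startsWith(labs, "lacZ")) && xgal) return("blue")
  "white"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a one-pot Golden Gate assembly
#'
#' Digests every part with the assembly enzyme, enumerates all stable and
#' unstable circular products (see [assemble_fragments()]), classifies each
#' (final vector; recircularized destination; re-ligated entry vector;
#' other by-product), marks stability (a product is stable iff the enzyme
#' has no remaining cleavable site) and predicts the screening color.
#' Products are sorted deterministically: final vectors first, then by
#' length, then by canonical sequence.
#'
#' @param parts list of [ds_seq()] entry parts with roles set (`role` field:
#'   `up`, `down`, `cargo_resistance`, `destination`).  At most one
#'   destination.  Parts without a cleavable site are flagged inert and
#'   passed through unchanged.
#' @param enz assembly enzyme (type IIS, 4 nt 5' overhangs).  BtgZI is
#'   accepted but draws a warning: one-pot assembly with it could not be
#'   validated.
#' @param max_cycle maximum oriented fragments per circle (default 6).
#' @param xgal predict colors as if X-Gal were present.
#' @param report_dead_ends also report linear dead-end fragments that
#'   cannot enter any circle.
#' @return list of `assembly_product` objects (class `assembly_products`).
#' @export
golden_gate <- function(parts, enz, max_cycle = 6L, xgal = FALSE,
                        report_dead_ends = FALSE) {
  e <- enzyme(enz)
  if (e$kind != "IIS" || e$cut_bottom - e$cut_top != 4L)
    stop("assembly enzyme must be type IIS with 4 nt 5' overhangs")
  if (e$name == "BtgZI")
    warning("BtgZI is accepted by the engine but excluded from the ",
            "recommended set: one-pot assembly with it could not be validated")
  roles <- vapply(parts, function(p) p$role %||% "unspecified", character(1))
  if (sum(roles == "destination") > 1L) stop("at most one destination part")
  has_dest <- any(roles == "destination")

  frags <- list(); inert <- list()
  for (p in parts) {
    fr <- digest(p, e)
    if (length(fr) == 1L && isTRUE(fr[[1]]$meta$uncut)) {
      inert[[length(inert) + 1L]] <- p
    } else {
      frags <- c(frags, Filter(function(f) ds_length(f) > 0L, fr))
    }
  }

  # warn on interchangeable fragments (identical end pairs => isomers)
  keys <- vapply(frags, function(f)
    paste(f$left_end$polarity, f$left_end$overhang,
          f$right_end$polarity, f$right_end$overhang), character(1))
  dup <- duplicated(keys) | duplicated(keys, fromLast = TRUE)
  if (any(dup)) {
    dup_ids <- unique(vapply(frags[dup], function(f) f$id %||% "?", character(1)))
    if (length(dup_ids) > 1L)
      warning("ambiguous assembly: fragments from parts ",
              paste(dup_ids, collapse = ", "),
              " share identical end pairs and form isomeric products")
  }

  circles <- assemble_fragments(frags, max_cycle)
  products <- lapply(circles, function(circ) {
    stable <- nrow(find_sites(circ, e)) == 0L
    cls <- classify_product(circ, parts)
    junctions <- circ$features[circ$features$label == "junction", , drop = FALSE]
    scars <- vapply(seq_len(nrow(junctions)), function(i)
      ds_slice(circ, junctions$start[i], junctions$end[i]), character(1))
    structure(list(
      sequence = circ, classification = cls,
      predicted_color = predict_color(circ, xgal),
      stable = stable, length = ds_length(circ),
      junction_scars = scars,
      members = vapply(circ$meta$members, function(mm) mm$id %||% "?", character(1))
    ), class = "assembly_product")
  })

  if (length(inert)) {
    for (p in inert) {
      products[[length(products) + 1L]] <- structure(list(
        sequence = p, classification = "other_byproduct",
        predicted_color = predict_color(p, xgal),
        stable = TRUE, length = ds_length(p),
        junction_scars = character(), members = p$id %||% "?",
        inert = TRUE
      ), class = "assembly_product")
    }
  }

  cls <- vapply(products, `[[`, character(1), "classification")
  lens <- vapply(products, `[[`, numeric(1), "length")
  keys <- vapply(products, function(p)
    if (p$sequence$topology == "circular") ds_canonical(p$sequence) else p$sequence$bases,
    character(1))
  ord <- order(cls != "final_vector", lens, keys)
  products <- products[ord]

  if (has_dest && length(parts) > 1L && !any(cls == "final_vector")) {
    dest_part <- parts[[match("destination", roles)]]
    missing_roles <- setdiff(c("up", "down", "cargo_resistance"), roles)
    diag <- diagnose_missing_junctions(frags, dest_part)
    stop("no final vector constructible: ",
         if (length(missing_roles))
           paste0("missing part role(s) ", paste(missing_roles, collapse = ", "), "; ")
         else "",
         diag)
  }

  if (report_dead_ends) {
    attr(products, "dead_ends") <- dead_end_fragments(frags)
  }
  structure(products, class = "assembly_products")
}

diagnose_missing_junctions <- function(frags, dest_part) {
  bb <- Filter(function(f) has_feature(f, "bla"), frags)
  if (!length(bb)) return("destination backbone fragment (bla) not produced by digestion")
  bb <- bb[[1]]
  unmatched <- character()
  for (side in c("left", "right")) {
    end <- if (side == "left") bb$left_end else bb$right_end
    partners <- vapply(frags, function(f) {
      if (identical(f, bb)) return(FALSE)
      for (o in c("+", "-")) {
        oe <- oriented_ends(f, o)
        if (side == "left" && ends_compatible(oe$right, end)) return(TRUE)
        if (side == "right" && ends_compatible(end, oe$left)) return(TRUE)
      }
      FALSE
    }, logical(1))
    if (!any(partners))
      unmatched <- c(unmatched, sprintf("backbone %s end (%s) has no partner",
                                        side, end$overhang))
  }
  if (length(unmatched)) paste(unmatched, collapse = "; ")
  else "all backbone junctions have partners but no closed cycle exists"
}

dead_end_fragments <- function(frags) {
  m <- length(frags)
  if (!m) return(list())
  in_cycle <- rep(FALSE, m)
  circles <- assemble_fragments(frags, 6L)
  for (circ in circles) {
    ids <- as.integer(sub("[+-]$", "", circ$meta$cycle))
    in_cycle[ids] <- TRUE
  }
  frags[!in_cycle]
}

#' @export
print.assembly_product <- function(x, ...) {
  cat(sprintf("<%s, %d bp, %s, %s, members: %s>\n", x$classification,
              x$length, if (x$stable) "stable" else "re-cleavable",
              x$predicted_color, paste(x$members, collapse = "+")))
  invisible(x)
}

#' @export
print.assembly_products <- function(x, ...) {
  cat(sprintf("%d assembly product(s):\n", length(x)))
  for (p in x) print(p)
  invisible(x)
}

#' Tabular summary of assembly products
#' @param products result of [golden_gate()].
#' @return data.frame (classification, length, color, stable, members).
#' @export
assembly_summary <- function(products) {
  data.frame(
    classification = vapply(products, `[[`, character(1), "classification"),
    length = vapply(products, `[[`, numeric(1), "length"),
    color = vapply(products, `[[`, character(1), "predicted_color"),
    stable = vapply(products, `[[`, logical(1), "stable"),
    members = vapply(products, function(p) paste(p$members, collapse = "+"),
                     character(1)),
    stringsAsFactors = FALSE)
}
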