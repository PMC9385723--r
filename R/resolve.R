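# Double-bifurcation resolution of a unitig graph with long-read support,
# and Eulerian reconstruction of the circular master molecule.
#
# States are oriented segments ("id|+" / "id|-"). Every bidirected link
# yields two directed arcs: (f,fo)->(t,to) and (t,!to)->(f,!fo); an
# Eulerian circuit uses each link (arc pair) exactly once.

state_key <- function(id, orient) paste0(id, "|", orient)

## directed arc table: both traversal directions of every canonical link
directed_arcs <- function(g) {
  l <- g$links
  if (nrow(l) == 0L)
    return(data.frame(from = character(), from_orient = character(),
                      to = character(), to_orient = character(),
                      overlap = integer(), link = integer()))
  fwd <- data.frame(from = l$from, from_orient = l$from_orient,
                    to = l$to, to_orient = l$to_orient,
                    overlap = l$overlap, link = seq_len(nrow(l)),
                    stringsAsFactors = FALSE)
  rev <- data.frame(from = l$to, from_orient = flip_orient(l$to_orient),
                    to = l$from, to_orient = flip_orient(l$from_orient),
                    overlap = l$overlap, link = seq_len(nrow(l)),
                    stringsAsFactors = FALSE)
  out <- rbind(fwd, rev)
  out[!duplicated(out[c("from", "from_orient", "to", "to_orient", "link")]), ,
      drop = FALSE]
}

#' Find double-bifurcation structures (DBSs)
#'
#' A DBS is a collapsed-repeat segment with at least two distinct entries
#' into and two distinct exits out of its forward orientation (the
#' `'>  =  <'` shape). Segments linked to themselves are skipped.
#'
#' @param g a [unitig_graph()].
#' @return list of DBS objects `list(repeat_segment, entries, exits)`,
#'   ordered by segment id; entries/exits are data.frames `(id, orient)`.
#' @export
find_dbs <- function(g) {
  arcs <- directed_arcs(g)
  out <- list()
  for (s in sort(names(g$segments))) {
    inn <- arcs[arcs$to == s & arcs$to_orient == "+", c("from", "from_orient")]
    outn <- arcs[arcs$from == s & arcs$from_orient == "+", c("to", "to_orient")]
    inn <- unique(inn)
    outn <- unique(outn)
    if (s %in% c(inn$from, outn$to)) next   # self-linked (tandem-style)
    if (nrow(inn) >= 2L && nrow(outn) >= 2L) {
      names(inn) <- names(outn) <- c("id", "orient")
      rownames(inn) <- rownames(outn) <- NULL
      inn <- inn[order(inn$id, inn$orient), , drop = FALSE]
      outn <- outn[order(outn$id, outn$orient), , drop = FALSE]
      out[[length(out) + 1L]] <- list(repeat_segment = s, entries = inn,
                                      exits = outn)
    }
  }
  out
}

perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms(n - 1L)) for (i in seq_len(n))
    out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  out
}

## overlap of the link connecting two states, NA if absent
arc_overlap <- function(arcs, from, fo, to, to_or) {
  hit <- arcs$overlap[arcs$from == from & arcs$from_orient == fo &
                      arcs$to == to & arcs$to_orient == to_or]
  if (length(hit)) hit[1] else NA_integer_
}

#' Enumerate junction candidates for a DBS
#'
#' One candidate per perfect matching of entries to exits (n! matchings;
#' capped at n = 4). Each matched pair gets the sequence
#' `last flank bp of entry + repeat + first flank bp of exit`, with
#' orientations applied and link overlaps trimmed once. Entry/exit
#' segments shorter than `flank` are used in full and the shortfall
#' recorded.
#'
#' @param g a [unitig_graph()].
#' @param d a DBS from [find_dbs()].
#' @param flank flank length in bp (> 0).
#' @return list of candidates `list(dbs, perm, pairs, support)`.
#' @export
enumerate_junctions <- function(g, d, flank = 1000L) {
  stopifnot(flank > 0L)
  n <- nrow(d$entries)
  if (n != nrow(d$exits))
    stop("DBS at ", d$repeat_segment, ": entries and exits differ in number")
  if (n > 4L)
    stop("DBS at ", d$repeat_segment, " has ", n,
         " entries; repeats above copy number 4 are not supported")
  arcs <- directed_arcs(g)
  rep_seq <- g$segments[[d$repeat_segment]]$seq
  out <- list()
  for (perm in perms(n)) {
    pairs <- vector("list", n)
    for (i in seq_len(n)) {
      e <- d$entries[i, ]
      x <- d$exits[perm[i], ]
      ov_in <- arc_overlap(arcs, e$id, e$orient, d$repeat_segment, "+")
      ov_out <- arc_overlap(arcs, d$repeat_segment, "+", x$id, x$orient)
      ent_full <- oriented_seq(g, e$id, e$orient)
      ent <- substr(ent_full, max(1L, nchar(ent_full) - flank + 1L),
                    nchar(ent_full))
      rep_tr <- substr(rep_seq, ov_in + 1L, nchar(rep_seq))
      ex_full <- substr(oriented_seq(g, x$id, x$orient), ov_out + 1L,
                        nchar(oriented_seq(g, x$id, x$orient)))
      ex <- substr(ex_full, 1L, min(flank, nchar(ex_full)))
      pairs[[i]] <- list(entry = e, exit = x,
                         seq = paste0(ent, rep_tr, ex),
                         entry_len = nchar(ent), repeat_len = nchar(rep_tr),
                         exit_len = nchar(ex),
                         shortfall = (nchar(ent) < flank) || (nchar(ex) < flank))
    }
    out[[length(out) + 1L]] <- list(dbs = d, perm = perm, pairs = pairs,
                                    support = rep(NA_integer_, n))
  }
  out
}

## does one read support one junction sequence? anchors = exact k-mer
## matches chained on their modal diagonal; coverage must reach the
## effective span on both flanks
read_supports <- function(read_kmers, cand_kmers, k, entry_len, repeat_len,
                          cand_len, min_span) {
  idx <- match(read_kmers, cand_kmers)
  hit <- which(!is.na(idx))
  if (length(hit) == 0L) return(FALSE)
  cpos <- idx[hit]
  diag <- hit - cpos
  best <- as.integer(names(which.max(table(diag))))
  cpos <- sort(unique(cpos[diag == best]))
  if (length(cpos) == 0L) return(FALSE)
  covered <- unique(unlist(lapply(cpos, function(p) p:(p + k - 1L))))
  span_entry <- sum(covered <= entry_len)
  span_exit <- sum(covered > entry_len + repeat_len)
  span_entry >= min(min_span, entry_len) &&
    span_exit >= min(min_span, cand_len - entry_len - repeat_len)
}

#' Score junction candidates by long-read support
#'
#' A read supports a matched pair when a chain of exact k-mer anchors on a
#' common diagonal (either strand) covers at least `min_span` bp of the
#' entry flank and at least `min_span` bp of the exit flank (clamped to
#' the available flank length). Each read counts at most once per pair.
#'
#' @param candidates output of [enumerate_junctions()].
#' @param reads list of reads (`list(id, seq)`).
#' @param k anchor length (>= 11).
#' @param min_span required anchored span on each side of the repeat, bp.
#' @return candidates with `support` (per pair) filled in.
#' @export
map_support <- function(candidates, reads, k = 15L, min_span = 200L) {
  stopifnot(k >= 11L)
  read_km <- lapply(reads, function(r) {
    list(fwd = kmer_vector(r$seq, k), rev = kmer_vector(revcomp(r$seq), k))
  })
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    supp <- integer(length(cand$pairs))
    for (pi in seq_along(cand$pairs)) {
      p <- cand$pairs[[pi]]
      ck <- kmer_vector(p$seq, k)
      n_sup <- 0L
      for (rk in read_km) {
        ok <- read_supports(rk$fwd, ck, k, p$entry_len, p$repeat_len,
                            nchar(p$seq), min_span) ||
              read_supports(rk$rev, ck, k, p$entry_len, p$repeat_len,
                            nchar(p$seq), min_span)
        if (ok) n_sup <- n_sup + 1L
      }
      supp[pi] <- n_sup
    }
    candidates[[ci]]$support <- supp
  }
  candidates
}

pairing_label <- function(cand) {
  paste(vapply(cand$pairs, function(p)
    sprintf("%s%s>%s%s", p$entry$id, p$entry$orient, p$exit$id, p$exit$orient),
    ""), collapse = ",")
}

#' Resolve all DBSs in a unitig graph using read support
#'
#' DBSs are processed in deterministic (segment-id) order and re-detected
#' after each resolution. For each DBS the matching with the largest total
#' support wins; the repeat segment is duplicated so each entry runs
#' through its own copy to its matched exit. Ties are broken toward the
#' lexicographically smallest concatenated candidate sequence and flagged
#' `LOW_CONFIDENCE`; all-zero support leaves the DBS intact, flagged
#' `UNRESOLVED`.
#'
#' @param g a [unitig_graph()].
#' @param reads list of long reads.
#' @param k,min_span,flank see [map_support()] and [enumerate_junctions()].
#' @param max_iter safety cap on resolution rounds.
#' @return `list(graph, decisions)`; decisions has one row per DBS with the
#'   support of every pairing.
#' @export
resolve_graph <- function(g, reads, k = 15L, min_span = 200L, flank = 1000L,
                          max_iter = 100L) {
  decisions <- list()
  skipped <- character(0)
  for (iter in seq_len(max_iter)) {
    dbss <- Filter(function(d) !(d$repeat_segment %in% skipped), find_dbs(g))
    if (length(dbss) == 0L) break
    d <- dbss[[1L]]
    cands <- map_support(enumerate_junctions(g, d, flank = flank), reads,
                         k = k, min_span = min_span)
    totals <- vapply(cands, function(cc) sum(cc$support), 0L)
    supp_str <- paste(vapply(cands, function(cc)
      sprintf("%s=%d", pairing_label(cc), sum(cc$support)), ""),
      collapse = ";")
    if (all(totals == 0L)) {
      skipped <- c(skipped, d$repeat_segment)
      decisions[[length(decisions) + 1L]] <- data.frame(
        dbs_segment = d$repeat_segment, pairing = NA_character_,
        support_per_pairing = supp_str, chosen = NA_character_,
        flag = "UNRESOLVED", stringsAsFactors = FALSE)
      next
    }
    best <- which(totals == max(totals))
    flag <- "OK"
    if (length(best) > 1L) {
      keys <- vapply(cands[best], function(cc)
        paste(vapply(cc$pairs, `[[`, "", "seq"), collapse = ""), "")
      best <- best[order(keys)][1L]
      flag <- "LOW_CONFIDENCE"
    } else best <- best[1L]
    chosen <- cands[[best]]
    g <- apply_resolution(g, d, chosen)
    decisions[[length(decisions) + 1L]] <- data.frame(
      dbs_segment = d$repeat_segment, pairing = pairing_label(chosen),
      support_per_pairing = supp_str, chosen = pairing_label(chosen),
      flag = flag, stringsAsFactors = FALSE)
  }
  dec <- if (length(decisions)) do.call(rbind, decisions)
         else data.frame(dbs_segment = character(), pairing = character(),
                         support_per_pairing = character(),
                         chosen = character(), flag = character())
  list(graph = g, decisions = dec)
}

## duplicate the repeat segment of a DBS along the chosen matching
apply_resolution <- function(g, d, chosen) {
  arcs <- directed_arcs(g)
  s <- d$repeat_segment
  segs <- g$segments
  n <- length(chosen$pairs)
  cov <- segs[[s]]$cov
  new_links <- list()
  for (i in seq_len(n)) {
    p <- chosen$pairs[[i]]
    nid <- sprintf("%s~%d", s, i)
    segs[[nid]] <- list(seq = segs[[s]]$seq,
                        cov = if (is.null(cov) || is.na(cov)) NA_real_ else cov / n)
    ov_in <- arc_overlap(arcs, p$entry$id, p$entry$orient, s, "+")
    ov_out <- arc_overlap(arcs, s, "+", p$exit$id, p$exit$orient)
    new_links[[length(new_links) + 1L]] <- data.frame(
      from = p$entry$id, from_orient = p$entry$orient,
      to = nid, to_orient = "+", overlap = ov_in, stringsAsFactors = FALSE)
    new_links[[length(new_links) + 1L]] <- data.frame(
      from = nid, from_orient = "+",
      to = p$exit$id, to_orient = p$exit$orient, overlap = ov_out,
      stringsAsFactors = FALSE)
  }
  segs[[s]] <- NULL
  keep <- g$links[g$links$from != s & g$links$to != s, , drop = FALSE]
  unitig_graph(segs, rbind(keep, do.call(rbind, new_links)))
}

#' Find a cyclic path covering every link exactly once
#'
#' Hierholzer's algorithm on the bidirected graph: a circular walk through
#' oriented segments using each link-equivalence class exactly once.
#' Deterministic: arcs are tried in lexicographic order and the output is
#' rotated to start at the smallest segment id in forward orientation when
#' possible.
#'
#' @param g a resolved [unitig_graph()].
#' @return `list(path, circular = TRUE)` where path is a data.frame
#'   `(segment, orient)`.
#' @export
cyclic_path <- function(g) {
  arcs <- directed_arcs(g)
  if (nrow(arcs) == 0L) stop("graph has no links; no cyclic path exists")
  arcs <- arcs[order(arcs$from, arcs$from_orient, arcs$to, arcs$to_orient), ,
               drop = FALSE]
  n_links <- nrow(g$links)
  used <- rep(FALSE, n_links)
  from_key <- state_key(arcs$from, arcs$from_orient)

  start_seg <- sort(unique(c(arcs$from)))[1]
  start <- state_key(start_seg, "+")
  if (!start %in% from_key) start <- from_key[1]

  stack <- list(start)
  circuit <- character(0)
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]
    cand <- which(from_key == v & !used[arcs$link])
    if (length(cand) > 0L) {
      a <- cand[1L]
      used[arcs$link[a]] <- TRUE
      stack[[length(stack) + 1L]] <- state_key(arcs$to[a], arcs$to_orient[a])
    } else {
      circuit <- c(circuit, v)
      stack[[length(stack)]] <- NULL
    }
  }
  if (!all(used)) {
    left <- unique(c(g$links$from[!used], g$links$to[!used]))
    stop("no Eulerian circuit: unused links at segment(s) ",
         paste(sort(left), collapse = ", "))
  }
  circuit <- rev(circuit)
  if (circuit[1] != circuit[length(circuit)])
    stop("no Eulerian circuit: walk is not closed")
  circuit <- circuit[-length(circuit)]
  parts <- do.call(rbind, strsplit(circuit, "|", fixed = TRUE))
  path <- data.frame(segment = parts[, 1], orient = parts[, 2],
                     stringsAsFactors = FALSE)
  # canonical rotation: smallest segment id, forward orientation if present
  pref <- which(path$orient == "+")
  anchor <- if (length(pref)) pref[order(path$segment[pref])][1L]
            else order(path$segment)[1L]
  if (anchor > 1L)
    path <- rbind(path[anchor:nrow(path), , drop = FALSE],
                  path[seq_len(anchor - 1L), , drop = FALSE])
  rownames(path) <- NULL
  list(path = path, circular = TRUE)
}

#' Spell the circular sequence of a resolved path
#'
#' Concatenates oriented segment sequences, trimming each link overlap
#' once per junction (including the closing junction). The claimed overlap
#' bases are verified.
#'
#' @param g a [unitig_graph()].
#' @param p a path from [cyclic_path()].
#' @return a circular [genome()].
#' @export
path_to_sequence <- function(g, p) {
  arcs <- directed_arcs(g)
  path <- p$path
  n <- nrow(path)
  pieces <- character(n)
  for (i in seq_len(n)) {
    prev <- if (i == 1L) n else i - 1L
    ov <- arc_overlap(arcs, path$segment[prev], path$orient[prev],
                      path$segment[i], path$orient[i])
    if (is.na(ov))
      stop("path steps ", prev, "->", i, " are not connected by a link")
    cur <- oriented_seq(g, path$segment[i], path$orient[i])
    if (ov > 0L) {
      prv <- oriented_seq(g, path$segment[prev], path$orient[prev])
      if (substr(prv, nchar(prv) - ov + 1L, nchar(prv)) !=
          substr(cur, 1L, ov))
        stop("inconsistent overlap (", ov, " bp) between ",
             path$segment[prev], " and ", path$segment[i])
    }
    pieces[i] <- substr(cur, ov + 1L, nchar(cur))
  }
  genome("resolved", paste(pieces, collapse = ""), circular = TRUE)
}
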