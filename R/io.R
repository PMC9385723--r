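#' Read a FASTA file into a list of genomes
#'
#' The header token before the first whitespace becomes the genome id.
#' Records are linear by default; set `circular = TRUE` to mark all records
#' circular (FASTA itself carries no topology).
#'
#' @param path FASTA file.
#' @param circular mark the loaded genomes circular.
#' @return list of [genome()] objects, input order preserved.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  ss <- Biostrings::readBStringSet(path)   # BString: keep bytes, validate ourselves
  if (length(ss) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  out <- vector("list", length(ss))
  for (i in seq_along(ss))
    out[[i]] <- genome(ids[i], as.character(ss[[i]]), circular = circular)
  out
}

#' Write genomes to a FASTA file
#'
#' Sequence lines wrap at 70 columns (fixed, for reproducible round trips).
#'
#' @param genomes a `genome` or list of them.
#' @param path output file.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    writeLines(paste0(">", g$id), con)
    L <- nchar(g$seq)
    starts <- seq(1L, L, by = 70L)
    writeLines(substring(g$seq, starts, pmin(starts + 69L, L)), con)
  }
  invisible(path)
}

#' Read a FASTQ file of long reads
#' @param path FASTQ file (4-line records, uncompressed).
#' @return list of reads, each `list(id, seq, qual)`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  if (length(ln) %% 4L != 0L) stop("truncated FASTQ: ", path)
  idx <- seq(1L, length(ln), by = 4L)
  lapply(idx, function(i) {
    if (substr(ln[i], 1, 1) != "@") stop("malformed FASTQ header at line ", i)
    list(id = sub("\\s.*$", "", substring(ln[i], 2L)),
         seq = toupper(ln[i + 1L]), qual = ln[i + 3L])
  })
}

#' Write long reads to FASTQ
#' @param reads list of `list(id, seq, qual)`; missing qualities become `I`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in reads) {
    q <- r$qual
    if (is.null(q)) q <- strrep("I", nchar(r$seq))
    writeLines(c(paste0("@", r$id), r$seq, "+", q), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# GenBank flat file (minimal: LOCUS topology, gene/CDS/tRNA/rRNA features
# with join/complement locations, ORIGIN sequence)

parse_gb_location <- function(loc, circular, L = NA_integer_) {
  strand <- "+"
  s <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", s)) {
    strand <- "-"
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  s <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  iv <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("^\\d+$", p)) return(c(as.integer(p), as.integer(p)))
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) != 3L) stop("unsupported GenBank location: ", loc)
    c(as.integer(m[2]), as.integer(m[3]))
  })
  iv <- do.call(rbind, iv)
  if (any(iv[, 2] < iv[, 1]) && !circular)
    stop("location spans the origin but topology is not circular: ", loc)
  list(strand = strand, intervals = iv)
}

#' Read a GenBank flat file
#'
#' Parses the LOCUS topology, `gene`/`CDS`/`tRNA`/`rRNA` features (with
#' `join`/`complement` locations mapped to multi-interval features) and the
#' ORIGIN sequence. Coordinates are kept 1-based inclusive, matching the
#' package-wide convention. Feature names come from the `/gene` qualifier,
#' falling back to `/product` then `/locus_tag`.
#'
#' @param path GenBank flat file.
#' @return a [genome()] with `features` populated.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  locus <- grep("^LOCUS", ln, value = TRUE)
  circular <- length(locus) > 0L && grepl("circular", locus[1], ignore.case = TRUE)
  id <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
        else "genbank_record"

  ori <- grep("^ORIGIN", ln)
  if (length(ori) == 0L) stop("GenBank record has no ORIGIN section: ", path)
  end <- grep("^//", ln)
  end <- if (length(end)) end[end > ori[1]][1] else length(ln) + 1L
  seq_lines <- ln[(ori[1] + 1L):(end - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_start <- grep("^FEATURES", ln)
  feats <- NULL
  if (length(feat_start)) {
    block <- ln[(feat_start[1] + 1L):(ori[1] - 1L)]
    # a feature line has a key in columns 6-20; continuation lines are blank there
    is_key <- grepl("^\\s{5}\\S", block)
    key_idx <- which(is_key)
    rows <- list()
    for (j in seq_along(key_idx)) {
      i0 <- key_idx[j]
      i1 <- if (j < length(key_idx)) key_idx[j + 1L] - 1L else length(block)
      key <- trimws(substr(block[i0], 1, 20))
      if (!key %in% c("gene", "CDS", "tRNA", "rRNA")) next
      body <- trimws(substring(block[i0:i1], 21L))
      # location = leading lines up to the first qualifier
      qual_at <- grep("^/", body)
      loc_lines <- if (length(qual_at)) body[seq_len(qual_at[1] - 1L)] else body
      loc <- paste(loc_lines, collapse = "")
      quals <- body[grepl("^/", body)]
      getq <- function(q) {
        hit <- grep(paste0("^/", q, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub('^"|"$', "", sub(paste0("^/", q, "="), "", hit[1]))
      }
      nm <- getq("gene")
      if (is.na(nm)) nm <- getq("product")
      if (is.na(nm)) nm <- getq("locus_tag")
      if (is.na(nm)) nm <- paste0(key, "_", j)
      pl <- parse_gb_location(loc, circular)
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, kind = if (key == "gene") "other" else key,
        strand = pl$strand,
        start = pl$intervals[, 1], end = pl$intervals[, 2],
        part = seq_len(nrow(pl$intervals)), stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      feats <- do.call(rbind, rows)
      # prefer gene rows; drop duplicate CDS/tRNA/rRNA rows for the same name
      # but keep their kind annotation on the gene rows
      kind_by_name <- tapply(feats$kind, feats$name,
                             function(k) {
                               k <- setdiff(unique(k), "other")
                               if (length(k)) k[1] else "other"
                             })
      is_gene_row <- feats$kind == "other"
      keep <- feats[is_gene_row | !(feats$name %in% feats$name[is_gene_row]), ,
                    drop = FALSE]
      keep <- keep[!duplicated(keep[c("name", "start", "end", "part")]), , drop = FALSE]
      keep$kind <- as.character(kind_by_name[keep$name])
      feats <- keep[order(keep$start, keep$name), , drop = FALSE]
      rownames(feats) <- NULL
    }
  }
  genome(id, seq, circular = circular, features = feats)
}

#' Write a genome with features as a GenBank flat file
#'
#' Emits LOCUS (with topology), gene features (complement/join locations),
#' and the ORIGIN sequence. Intended for synthetic annotated genomes and
#' round-trip testing, not for full GenBank fidelity.
#'
#' @param g a [genome()].
#' @param path output file.
#' @export
write_genbank <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (g$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   UNA 01-JAN-2000",
                     g$id, nchar(g$seq), topo), con)
  writeLines(sprintf("DEFINITION  %s, synthetic record.", g$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  if (!is.null(g$features) && nrow(g$features)) {
    sp <- split(g$features, g$features$name)
    sp <- sp[order(vapply(sp, function(d) min(d$start), 1))]
    for (d in sp) {
      d <- d[order(d$part), , drop = FALSE]
      locs <- sprintf("%d..%d", d$start, d$end)
      loc <- if (nrow(d) > 1L) paste0("join(", paste(locs, collapse = ","), ")")
             else locs
      if (d$strand[1] == "-") loc <- paste0("complement(", loc, ")")
      key <- if (d$kind[1] %in% c("CDS", "tRNA", "rRNA")) d$kind[1] else "gene"
      writeLines(sprintf("     %-16s%s", key, loc), con)
      writeLines(sprintf('                     /gene="%s"', d$name[1]), con)
    }
  }
  writeLines("ORIGIN", con)
  L <- nchar(g$seq)
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(g$seq, p, min(p + 59L, L))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GFA 1.0

#' Construct a unitig graph
#'
#' Bidirected sequence graph: `segments` is a named list of
#' `list(seq, cov)` and `links` a data.frame with columns `from`,
#' `from_orient`, `to`, `to_orient`, `overlap` (bp, exact match).
#' Traversing a link in reverse flips both orientations; the two
#' representations denote the same link.
#'
#' @param segments named list of `list(seq = <string>, cov = <numeric|NA>)`.
#' @param links data.frame as described above.
#' @return object of class `unitig_graph`.
#' @export
unitig_graph <- function(segments, links) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (nrow(links)) {
    stopifnot(all(c("from", "from_orient", "to", "to_orient", "overlap")
                  %in% names(links)))
    unknown <- setdiff(c(links$from, links$to), names(segments))
    if (length(unknown))
      stop("link references unknown segment(s): ", paste(unknown, collapse = ", "))
    stopifnot(all(links$from_orient %in% c("+", "-")),
              all(links$to_orient %in% c("+", "-")))
    links <- canonical_links(links)
  }
  structure(list(segments = segments, links = links), class = "unitig_graph")
}

#' @export
print.unitig_graph <- function(x, ...) {
  cat(sprintf("<unitig_graph> %d segments (%s bp total), %d links\n",
              length(x$segments),
              format(sum(vapply(x$segments, function(s) nchar(s$seq), 1)),
                     big.mark = ","),
              nrow(x$links)))
  invisible(x)
}

flip_orient <- function(o) ifelse(o == "+", "-", "+")

## one canonical representation per bidirected link; dedupe
canonical_links <- function(links) {
  a <- paste(links$from, links$from_orient, links$to, links$to_orient)
  b <- paste(links$to, flip_orient(links$to_orient),
             links$from, flip_orient(links$from_orient))
  swap <- b < a
  out <- links
  out$from[swap] <- links$to[swap]
  out$from_orient[swap] <- flip_orient(links$to_orient[swap])
  out$to[swap] <- links$from[swap]
  out$to_orient[swap] <- flip_orient(links$from_orient[swap])
  out <- out[!duplicated(out[c("from", "from_orient", "to", "to_orient", "overlap")]), ,
             drop = FALSE]
  out <- out[order(out$from, out$from_orient, out$to, out$to_orient), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GFA 1.0 unitig graph
#'
#' Parses `S` and `L` lines. Overlaps must be exact-match CIGARs (`55M`,
#' `0M`, or `*` meaning 0). Coverage is taken from `dp`/`DP` (depth) or
#' `RC` (read count, divided by segment length) tags when present.
#'
#' @param path GFA file.
#' @return a [unitig_graph()].
#' @export
read_gfa <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  segs <- list()
  link_rows <- list()
  for (l in ln) {
    if (!nzchar(l)) next
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (f[1] == "S") {
      if (length(f) < 3L) stop("malformed S line: ", l)
      cov <- NA_real_
      tags <- f[-(1:3)]
      dp <- grep("^(dp|DP):f:", tags, value = TRUE)
      rc <- grep("^RC:i:", tags, value = TRUE)
      if (length(dp)) cov <- as.numeric(sub("^..:f:", "", dp[1]))
      else if (length(rc)) cov <- as.numeric(sub("^RC:i:", "", rc[1])) / nchar(f[3])
      segs[[f[2]]] <- list(seq = toupper(f[3]), cov = cov)
    } else if (f[1] == "L") {
      if (length(f) < 6L) stop("malformed L line: ", l)
      ov_str <- f[6]
      ov <- if (ov_str == "*") 0L
            else if (grepl("^\\d+M$", ov_str)) as.integer(sub("M$", "", ov_str))
            else stop("non-numeric or non-exact overlap '", ov_str, "' in: ", l)
      link_rows[[length(link_rows) + 1L]] <-
        data.frame(from = f[2], from_orient = f[3], to = f[4], to_orient = f[5],
                   overlap = ov, stringsAsFactors = FALSE)
    }
  }
  if (length(segs) == 0L) stop("GFA file has no segments: ", path)
  links <- if (length(link_rows)) do.call(rbind, link_rows)
           else data.frame(from = character(), from_orient = character(),
                           to = character(), to_orient = character(),
                           overlap = integer(), stringsAsFactors = FALSE)
  unitig_graph(segs, links)
}

#' Write a unitig graph as GFA 1.0
#' @param g a [unitig_graph()].
#' @param path output file.
#' @export
write_gfa <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  for (id in sort(names(g$segments))) {
    s <- g$segments[[id]]
    tag <- if (!is.null(s$cov) && !is.na(s$cov)) sprintf("\tdp:f:%g", s$cov) else ""
    writeLines(sprintf("S\t%s\t%s%s", id, s$seq, tag), con)
  }
  if (nrow(g$links))
    writeLines(sprintf("L\t%s\t%s\t%s\t%s\t%dM",
                       g$links$from, g$links$from_orient,
                       g$links$to, g$links$to_orient, g$links$overlap), con)
  invisible(path)
}

## oriented segment sequence
oriented_seq <- function(g, id, orient) {
  s <- g$segments[[id]]$seq
  if (orient == "+") s else revcomp(s)
}

# ---------------------------------------------------------------------------
# report writers

#' Write a data.frame as a UTF-8 TSV report (header row, no quoting)
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a list as a JSON report
#' @param x list.
#' @param path output file.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
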