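# Readers and writers for the formats the pipeline touches: GFA 1 as the
# modern interchange for contig graphs, a tab-separated "454AllContigGraph"
# style dialect for Newbler output, FASTA contig sequences, and the TSV
# mate-pair candidate-link table.

gfa_tag <- function(fields, tag) {
  hit <- grep(paste0("^", tag, ":[A-Za-z]:"), fields, value = TRUE)
  if (!length(hit)) return(NA_character_)
  sub(paste0("^", tag, ":[A-Za-z]:"), "", hit[1L])
}

#' Read a contig graph from GFA 1
#'
#' S records become contigs; length is taken from the `LN:i:` tag or from the
#' sequence, and mean read depth must be carried in a `DP:f:` tag.  L records
#' become end-to-end edges: with `+`/`+` orientation the 3' end of the source
#' joins the 5' end of the target, and a `-` flips the respective end.
#' Spanning-read support is read from `RC:i:`, and a gap/insert base at the
#' join from `gp:i:` / `gb:Z:` tags.
#'
#' @param path Path to a GFA 1 file.
#' @return A [contig_graph].
#' @export
read_gfa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("read_gfa: empty file: ", path)
  recs <- strsplit(lines, "\t", fixed = TRUE)
  type <- vapply(recs, `[[`, character(1), 1L)

  s_recs <- recs[type == "S"]
  if (!length(s_recs)) stop("read_gfa: no S records in ", path)
  nodes <- do.call(rbind, lapply(s_recs, function(f) {
    id <- f[2L]
    seq <- if (length(f) >= 3L && f[3L] != "*") f[3L] else NA_character_
    ln <- gfa_tag(f, "LN")
    len <- if (!is.na(ln)) as.integer(ln) else if (!is.na(seq)) nchar(seq) else
      stop("read_gfa: segment ", id, " has neither sequence nor LN tag")
    dp <- gfa_tag(f, "DP")
    if (is.na(dp)) stop("read_gfa: segment ", id, " is missing the DP depth tag")
    rc <- gfa_tag(f, "RC")
    data.frame(contig_id = id, length = len, depth = as.numeric(dp),
               sequence = seq,
               num_reads = if (is.na(rc)) NA_integer_ else as.integer(rc),
               stringsAsFactors = FALSE)
  }))

  l_recs <- recs[type == "L"]
  edges <- if (length(l_recs)) {
    do.call(rbind, lapply(l_recs, function(f) {
      if (length(f) < 5L) stop("read_gfa: malformed L record")
      gp <- gfa_tag(f, "gp")
      gb <- gfa_tag(f, "gb")
      rc <- gfa_tag(f, "RC")
      data.frame(
        a_id = f[2L], a_end = if (f[3L] == "+") END3 else END5,
        b_id = f[4L], b_end = if (f[5L] == "+") END5 else END3,
        support = if (is.na(rc)) 0L else as.integer(rc),
        gap = if (is.na(gp)) 0L else as.integer(gp),
        gap_base = gb,
        stringsAsFactors = FALSE
      )
    }))
  } else NULL
  if (!is.null(edges)) {
    unknown <- setdiff(c(edges$a_id, edges$b_id), nodes$contig_id)
    if (length(unknown)) {
      stop("read_gfa: L record references unknown segment: ",
           paste(unique(unknown), collapse = ", "))
    }
  }
  contig_graph(nodes, edges)
}

#' Write a contig graph as GFA 1
#'
#' Emits a header, one S record per contig (sequence or `*`, `LN:i:` length,
#' `DP:f:` depth, optional `RC:i:` read count) and one L record per edge, in
#' deterministic order (contigs sorted by id, edges by canonical endpoint
#' tuple).  Depth is printed with enough digits to round-trip exactly.
#'
#' @param graph A [contig_graph].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "contig_graph"))
  out <- "H\tVN:Z:1.0"
  n <- graph$nodes[order(graph$nodes$contig_id), , drop = FALSE]
  if (nrow(n)) {
    s <- sprintf("S\t%s\t%s\tLN:i:%d\tDP:f:%s",
                 n$contig_id,
                 ifelse(is.na(n$sequence), "*", n$sequence),
                 n$length,
                 sprintf("%.17g", n$depth))
    has_nr <- !is.na(n$num_reads)
    s[has_nr] <- paste0(s[has_nr], sprintf("\tRC:i:%d", n$num_reads[has_nr]))
    out <- c(out, s)
  }
  e <- graph$edges
  if (nrow(e)) {
    l <- sprintf("L\t%s\t%s\t%s\t%s\t*\tRC:i:%d",
                 e$a_id, ifelse(e$a_end == END3, "+", "-"),
                 e$b_id, ifelse(e$b_end == END5, "+", "-"),
                 e$support)
    has_gap <- e$gap >= 1L
    l[has_gap] <- paste0(l[has_gap],
                         sprintf("\tgp:i:%d\tgb:Z:%s",
                                 e$gap[has_gap], e$gap_base[has_gap]))
    out <- c(out, l)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a Newbler-style "454AllContigGraph" table
#'
#' The vendor format is not publicly specified; this reader accepts a
#' documented dialect carrying exactly the fields the pipeline uses.  Rows
#' whose first field is `C` are contigs (`C <index> <contig_id> <length>
#' <depth>`); rows starting `L` or `I` are links (`<code> <contig_id>
#' <end 5|3> <contig_id> <end 5|3> <spanning-read count>`).  Any other
#' first-field code is skipped; skipped lines are counted and reported in one
#' warning and in the `"skipped"` attribute of the result.
#'
#' @param path Path to the tab-separated file.
#' @return A [contig_graph] with a `"skipped"` attribute (number of
#'   unrecognized lines).
#' @export
read_454_graph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("read_454_graph: empty file: ", path)
  recs <- strsplit(lines, "\t", fixed = TRUE)
  code <- vapply(recs, `[[`, character(1), 1L)

  nodes <- NULL
  is_c <- code == "C"
  if (any(is_c)) {
    nodes <- do.call(rbind, Map(function(f, ln) {
      if (length(f) < 5L) stop("read_454_graph: truncated contig row at line ", ln)
      len <- suppressWarnings(as.integer(f[4L]))
      dep <- suppressWarnings(as.numeric(f[5L]))
      if (is.na(len) || is.na(dep)) {
        stop("read_454_graph: non-numeric length/depth at line ", ln)
      }
      data.frame(contig_id = f[3L], length = len, depth = dep,
                 stringsAsFactors = FALSE)
    }, recs[is_c], lineno[is_c]))
  }

  is_l <- code %in% c("L", "I")
  edges <- if (any(is_l)) {
    do.call(rbind, Map(function(f, ln) {
      if (length(f) < 6L) stop("read_454_graph: truncated link row at line ", ln)
      if (!f[3L] %in% c("5", "3") || !f[5L] %in% c("5", "3")) {
        stop("read_454_graph: bad end code at line ", ln)
      }
      sup <- suppressWarnings(as.integer(f[6L]))
      if (is.na(sup)) stop("read_454_graph: non-numeric support at line ", ln)
      data.frame(a_id = f[2L], a_end = f[3L], b_id = f[4L], b_end = f[5L],
                 support = sup, stringsAsFactors = FALSE)
    }, recs[is_l], lineno[is_l]))
  } else NULL
  if (!is.null(edges)) {
    unknown <- setdiff(c(edges$a_id, edges$b_id),
                       if (is.null(nodes)) character(0) else nodes$contig_id)
    if (length(unknown)) {
      stop("read_454_graph: link references absent contig: ",
           paste(unique(unknown), collapse = ", "))
    }
  }

  n_skip <- sum(!is_c & !is_l)
  if (n_skip > 0L) {
    warning(sprintf("read_454_graph: skipped %d unrecognized record line(s)",
                    n_skip))
  }
  g <- contig_graph(nodes, edges)
  attr(g, "skipped") <- n_skip
  g
}

#' Read a mate-pair candidate-link table
#'
#' Expects a TSV with columns `repeat_id`, `link_count`, `five_prime_contig`,
#' `three_prime_contig` (header optional).  A blank `repeat_id` inherits the
#' last non-blank value, matching the layout of published link tables where
#' the repeat label is printed only on its first row.
#'
#' @param path Path to the TSV file.
#' @return A `link_table` data frame preserving row order.
#' @export
read_link_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("read_link_table: empty file: ", path)
  recs <- strsplit(lines, "\t", fixed = TRUE)
  # header detection: second column of the first row not an integer
  first_count <- suppressWarnings(as.numeric(trimws(recs[[1L]][2L])))
  if (is.na(first_count)) {
    recs <- recs[-1L]
    lineno <- lineno[-1L]
  }
  if (!length(recs)) stop("read_link_table: no data rows in ", path)
  rows <- Map(function(f, ln) {
    if (length(f) < 4L) stop("read_link_table: truncated row at line ", ln)
    cnt <- suppressWarnings(as.numeric(trimws(f[2L])))
    if (is.na(cnt) || cnt < 0 || cnt != floor(cnt)) {
      stop("read_link_table: link_count must be a non-negative integer at line ", ln)
    }
    data.frame(repeat_id = trimws(f[1L]), link_count = as.integer(cnt),
               five_prime_contig = trimws(f[3L]),
               three_prime_contig = trimws(f[4L]),
               stringsAsFactors = FALSE)
  }, recs, lineno)
  tab <- do.call(rbind, rows)
  # carry repeat_id down over blank rows
  for (i in seq_len(nrow(tab))) {
    if (!nzchar(tab$repeat_id[i])) {
      if (i == 1L) stop("read_link_table: first row has a blank repeat_id")
      tab$repeat_id[i] <- tab$repeat_id[i - 1L]
    }
  }
  link_table(tab)
}

#' Construct a link table from a data frame
#'
#' @param x Data frame with columns `repeat_id`, `link_count`,
#'   `five_prime_contig`, `three_prime_contig`.
#' @return The validated data frame with class `link_table`.
#' @export
link_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  req <- c("repeat_id", "link_count", "five_prime_contig", "three_prime_contig")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("link table is missing columns: ", paste(miss, collapse = ", "))
  x <- x[req]
  x$link_count <- as.integer(x$link_count)
  if (any(is.na(x$link_count)) || any(x$link_count < 0L)) {
    stop("link_count must be a non-negative integer")
  }
  key <- paste(x$repeat_id, x$five_prime_contig, x$three_prime_contig, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (repeat, 5'-contig, 3'-contig) row")
  rownames(x) <- NULL
  class(x) <- c("link_table", "data.frame")
  x
}

#' Attach contig sequences from a FASTA file
#'
#' FASTA record ids are matched to contig ids.  A record whose length
#' conflicts with the stated contig length is an error; FASTA records with no
#' matching contig produce a warning and are ignored; contigs without a FASTA
#' record keep an absent sequence.
#'
#' @param graph A [contig_graph].
#' @param fasta_path Path to a nucleotide FASTA file.
#' @return The graph with sequences filled in.
#' @export
attach_sequences <- function(graph, fasta_path) {
  stopifnot(inherits(graph, "contig_graph"))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  extra <- setdiff(ids, graph$nodes$contig_id)
  if (length(extra)) {
    warning("attach_sequences: FASTA record(s) with no matching contig: ",
            paste(extra, collapse = ", "))
  }
  hit <- ids %in% graph$nodes$contig_id
  for (i in which(hit)) {
    j <- match(ids[i], graph$nodes$contig_id)
    s <- normalize_sequence(as.character(seqs[[i]]), paste0("sequence ", ids[i]))
    if (nchar(s) != graph$nodes$length[j]) {
      stop(sprintf("attach_sequences: %s sequence length %d != stated length %d",
                   ids[i], nchar(s), graph$nodes$length[j]))
    }
    graph$nodes$sequence[j] <- s
  }
  contig_graph(graph$nodes, graph$edges)
}

#' Write a single circular sequence as FASTA
#'
#' @param sequence Nucleotide string.
#' @param path Output path.
#' @param name Record name.
#' @param circular Note circular topology in the description line.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(sequence, path, name = "assembly",
                               circular = TRUE) {
  set <- Biostrings::DNAStringSet(sequence)
  names(set) <- if (circular) paste(name, "[topology=circular]") else name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
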