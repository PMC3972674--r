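# Snapshot, bond-log and bond-network output: extended-XYZ frames readable
# by common molecular viewers, TSV event logs, DOT graphs.

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read snapshot records (extended XYZ)
#'
#' One frame per record: a count line; a comment line carrying the step,
#' seed, box extents and the bond list; then one line per particle with
#' `type x y z id group`. The round trip is lossless.
#'
#' @param record an `srbm_record` (see [as_record()]).
#' @param file output path or connection.
#' @param append append a frame to an existing trajectory file.
#' @return `file`, invisibly.
#' @export
write_snapshot <- function(record, file, append = FALSE) {
  p <- record$particles
  bonds <- record$bonds
  bstr <- if (nrow(bonds))
    paste(sprintf("%d:%s-%d:%s", bonds$particle_a, bonds$site_a,
                  bonds$particle_b, bonds$site_b), collapse = ";")
  else ""
  hdr <- sprintf("step=%d seed=%s box=%s bonds=%s",
                 record$step,
                 if (is.null(record$seed)) "NA" else as.character(record$seed),
                 paste(.fmt_num(as.numeric(record$box)), collapse = ","),
                 bstr)
  lines <- c(as.character(nrow(p)), hdr,
             if (nrow(p)) sprintf("%s %s %s %s %d %d", p$type,
                                  .fmt_num(p$x), .fmt_num(p$y), .fmt_num(p$z),
                                  p$id, ifelse(is.na(p$group), -1L, p$group)))
  if (append) cat(lines, file = file, sep = "\n", append = TRUE)
  else writeLines(lines, file)
  invisible(file)
}

#' @rdname write_snapshot
#' @param records list of `srbm_record` frames.
#' @export
write_trajectory <- function(records, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (r in records) write_snapshot(r, con, append = TRUE)
  invisible(file)
}

.parse_frame <- function(lines, at) {
  n <- suppressWarnings(as.integer(lines[at]))
  if (is.na(n) || n < 0) stop("malformed frame header at line ", at)
  if (at + 1 + n > length(lines) + 0)
    stop("frame at line ", at, ": count ", n, " exceeds available lines")
  hdr <- lines[at + 1]
  kv <- regmatches(hdr, gregexpr("[a-z]+=[^ ]*", hdr))[[1]]
  vals <- setNames(sub("^[a-z]+=", "", kv), sub("=.*$", "", kv))
  step <- as.integer(vals[["step"]])
  seed <- if (identical(vals[["seed"]], "NA")) NULL else
    as.integer(vals[["seed"]])
  box <- matrix(as.numeric(strsplit(vals[["box"]], ",")[[1]]), nrow = 2)
  bonds <- data.frame(particle_a = integer(), site_a = character(),
                      particle_b = integer(), site_b = character(),
                      stringsAsFactors = FALSE)
  if (nzchar(vals[["bonds"]])) {
    ends <- strsplit(strsplit(vals[["bonds"]], ";")[[1]], "-")
    parse_end <- function(e) strsplit(e, ":")[[1]]
    bonds <- do.call(rbind, lapply(ends, function(e) {
      a <- parse_end(e[1]); b <- parse_end(e[2])
      data.frame(particle_a = as.integer(a[1]), site_a = a[2],
                 particle_b = as.integer(b[1]), site_b = b[2],
                 stringsAsFactors = FALSE)
    }))
  }
  particles <- data.frame(id = integer(), type = character(), x = numeric(),
                          y = numeric(), z = numeric(), group = integer(),
                          stringsAsFactors = FALSE)
  if (n > 0) {
    toks <- strsplit(lines[at + 1 + seq_len(n)], " +")
    bad <- which(lengths(toks) != 6L)
    if (length(bad)) stop("malformed particle line ", at + 1 + bad[1])
    m <- do.call(rbind, toks)
    grp <- as.integer(m[, 6])
    particles <- data.frame(id = as.integer(m[, 5]), type = m[, 1],
                            x = as.numeric(m[, 2]), y = as.numeric(m[, 3]),
                            z = as.numeric(m[, 4]),
                            group = ifelse(grp < 0, NA_integer_, grp),
                            stringsAsFactors = FALSE)
  }
  rownames(bonds) <- NULL
  rec <- structure(list(step = step,
                        particles = particles[, c("id", "type", "x", "y",
                                                  "z", "group")],
                        bonds = bonds, box = box, seed = seed),
                   class = "srbm_record")
  list(record = rec, next_at = at + 2 + n)
}

#' @rdname write_snapshot
#' @param source input path or connection.
#' @export
read_snapshot <- function(source) {
  lines <- readLines(source)
  .parse_frame(lines, 1L)$record
}

#' @rdname write_snapshot
#' @export
read_trajectory <- function(source) {
  lines <- readLines(source)
  out <- list()
  at <- 1L
  while (at <= length(lines)) {
    fr <- .parse_frame(lines, at)
    out <- c(out, list(fr$record))
    at <- fr$next_at
  }
  out
}

#' Write / read a bond-event log
#'
#' Tab-separated, chronological: step, rule, particle/site pair, action
#' (`formed` / `broken`). The round trip is lossless.
#'
#' @param events bond-event data frame (see [run_protocol()]).
#' @param file output path.
#' @return `file` invisibly (writer); the event data frame (reader).
#' @export
write_bond_log <- function(events, file) {
  utils::write.table(events, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_bond_log
#' @param source input path.
#' @export
read_bond_log <- function(source) {
  df <- read.delim(source, stringsAsFactors = FALSE)
  need <- c("step", "rule", "particle_a", "site_a", "particle_b", "site_b",
            "action")
  if (!identical(names(df), need))
    stop("malformed bond log: expected columns ",
         paste(need, collapse = ", "))
  df
}

#' Export the bond network as DOT text
#'
#' One node per particle (labelled by its molecule type), one undirected
#' edge per bond (site bonds and structural template bonds alike), in
#' deterministic id order; renderable with graphviz.
#'
#' @param world an `srbm_world`.
#' @param file optional output path; when `NULL` the DOT text is returned.
#' @return DOT text (invisibly when written to `file`).
#' @export
write_bond_network <- function(world, file = NULL) {
  p <- world$particles[order(world$particles$id), ]
  bl <- bond_list(world)
  edges <- rbind(
    if (nrow(bl)) data.frame(a = bl$particle_a, b = bl$particle_b),
    if (nrow(world$struct_bonds)) data.frame(a = world$struct_bonds$p1,
                                             b = world$struct_bonds$p2))
  lines <- c("graph bonds {",
             sprintf('  n%d [label="%s"];', p$id, p$type),
             if (!is.null(edges) && nrow(edges)) {
               e <- edges[order(edges$a, edges$b), , drop = FALSE]
               sprintf("  n%d -- n%d;", pmin(e$a, e$b), pmax(e$a, e$b))
             },
             "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
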