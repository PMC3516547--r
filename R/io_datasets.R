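#' @useDynLib crm2gene, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom dnorm quantile var setNames
#' @importFrom utils read.delim write.table combn head
NULL

# Coordinate conventions, centralized here:
#   * intervals (CRMs, insulator peaks, signal segments): 0-based half-open
#     [start, end), the BED convention;
#   * TSS: 1-based point, the GFF convention.  Internally a TSS is converted
#     to the 0-based index of the base it occupies (pos - 1).

#' Read a CRM x binding-variable occupancy table
#'
#' The table must have a CRM identifier column (first column, or a column
#' named `crm_id`) and one numeric column per binding variable, e.g.
#' `twi_2-4h`.  Values are quantitative ChIP enrichments in arbitrary
#' non-negative units.
#'
#' @param path path to a TSV/CSV file with a header.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @return a numeric matrix of class `occupancy_matrix` with CRM ids as row
#'   names and binding-variable names as column names, column order as in
#'   the file.
#' @export
read_occupancy <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("occupancy file must have a CRM-id column and >= 1 binding variable")
  idcol <- if ("crm_id" %in% names(df)) "crm_id" else names(df)[1L]
  ids <- as.character(df[[idcol]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated CRM id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  vals <- df[setdiff(names(df), idcol)]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (is.character(v) || is.factor(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("non-numeric cell in occupancy file at row ", bad[1L],
             " (CRM '", ids[bad[1L]], "'), column '", names(vals)[j], "'")
      v <- vn
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  if (any(!is.finite(m))) {
    ij <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop("non-finite occupancy value at CRM '", ids[ij[1L]],
         "', column '", colnames(m)[ij[2L]], "'")
  }
  rownames(m) <- ids
  class(m) <- c("occupancy_matrix", class(m))
  m
}

#' Write an occupancy matrix as TSV
#' @param x occupancy matrix (CRM ids as row names).
#' @param path output path.
#' @export
write_occupancy <- function(x, path) {
  m <- unclass(x)
  df <- data.frame(crm_id = rownames(m),
                   apply(m, 2L, sprintf, fmt = "%.17g"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a genome layout from TSS, CRM and insulator tables
#'
#' The container that `build_link_table()` and
#' `discretize_promoter_signal()` consume.  Intervals are 0-based
#' half-open; TSS positions are 1-based points.
#'
#' @param tss data.frame with columns `gene_id`, `chrom`, `pos` (1-based),
#'   `strand` (`"+"`/`"-"`); one row per gene.
#' @param crms data.frame with columns `crm_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param insulators data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open); may be empty.
#' @return an object of class `genome_layout`.
#' @export
genome_layout <- function(tss, crms, insulators) {
  stopifnot(all(c("gene_id", "chrom", "pos", "strand") %in% names(tss)),
            all(c("crm_id", "chrom", "start", "end") %in% names(crms)),
            all(c("chrom", "start", "end") %in% names(insulators)))
  if (anyDuplicated(tss$gene_id))
    stop("duplicated gene_id in TSS table")
  if (anyDuplicated(crms$crm_id))
    stop("duplicated crm_id in CRM table")
  bad <- which(crms$start >= crms$end)
  if (length(bad))
    stop("malformed CRM interval (start >= end): ",
         paste(crms$crm_id[bad], collapse = ", "))
  if (nrow(insulators) && any(insulators$start >= insulators$end))
    stop("malformed insulator interval (start >= end)")
  structure(list(tss = tss, crms = crms, insulators = insulators),
            class = "genome_layout")
}

#' Read a genome layout from standard genomic files
#'
#' Gene models are read from GFF3/GTF (`type == "gene"` records; the TSS is
#' the strand-aware 5' end), CRM intervals and insulator peaks from BED.
#'
#' @param gff_path GFF3/GTF file of gene models.
#' @param crm_bed BED file of CRM intervals (name column = CRM id).
#' @param insulator_bed BED file of insulator peaks, or `NULL` for none.
#' @return a `genome_layout`.
#' @export
read_genome_layout <- function(gff_path, crm_bed, insulator_bed = NULL) {
  gr <- rtracklayer::import(gff_path)
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) == "gene"]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID)
         else if (!is.null(gr$gene_id)) as.character(gr$gene_id)
         else as.character(gr$Name)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  tss <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = ifelse(strand == "+", BiocGenerics::start(gr),
                 BiocGenerics::end(gr)),
    strand = strand, stringsAsFactors = FALSE)
  cr <- rtracklayer::import(crm_bed)
  crms <- data.frame(
    crm_id = if (!is.null(cr$name)) as.character(cr$name)
             else paste0("crm", seq_along(cr)),
    chrom = as.character(GenomicRanges::seqnames(cr)),
    start = BiocGenerics::start(cr) - 1L,
    end = BiocGenerics::end(cr), stringsAsFactors = FALSE)
  if (is.null(insulator_bed)) {
    ins <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  } else {
    ib <- rtracklayer::import(insulator_bed)
    ins <- data.frame(chrom = as.character(GenomicRanges::seqnames(ib)),
                      start = BiocGenerics::start(ib) - 1L,
                      end = BiocGenerics::end(ib),
                      stringsAsFactors = FALSE)
  }
  genome_layout(tss, crms, ins)
}

#' Tabulate CRM-gene links within a distance window
#'
#' One row per (CRM, gene) pair on the same chromosome with distance below
#' `window`.  Distance is measured from the TSS to the nearest CRM edge and
#' is 0 when the TSS falls inside the CRM.  The insulator count is the
#' number of insulator peaks whose midpoint lies strictly between the TSS
#' and the nearest CRM edge (peaks from all insulator factors pooled).
#'
#' @param layout a `genome_layout`.
#' @param window maximum distance in bp (exclusive); default 100 kb.
#' @return data.frame of class `link_table` with columns `crm_id`,
#'   `gene_id`, `distance`, `insulator_count`.
#' @export
build_link_table <- function(layout, window = 1e5) {
  stopifnot(inherits(layout, "genome_layout"), window > 0)
  tss <- layout$tss; crms <- layout$crms; ins <- layout$insulators
  gchr <- unique(tss$chrom); cchr <- unique(crms$chrom)
  if (!length(intersect(gchr, cchr)))
    stop("no shared chromosome between genes and CRMs; gene chroms: ",
         paste(gchr, collapse = ","), "; CRM chroms: ",
         paste(cchr, collapse = ","))
  out <- vector("list", length(gchr))
  for (ci in seq_along(gchr)) {
    ch <- gchr[ci]
    g <- tss[tss$chrom == ch, , drop = FALSE]
    cr <- crms[crms$chrom == ch, , drop = FALSE]
    if (!nrow(g) || !nrow(cr)) next
    mids <- numeric(0)
    if (nrow(ins)) {
      ii <- ins[ins$chrom == ch, , drop = FALSE]
      mids <- sort((ii$start + ii$end) / 2)
    }
    t0 <- g$pos - 1L                       # 0-based TSS base index
    # all pairs on this chromosome, vectorized over the CRM axis per gene
    res <- lapply(seq_len(nrow(g)), function(k) {
      t <- t0[k]
      # distance = number of bases strictly between the TSS base and the
      # nearest CRM base; 0 when the TSS lies inside the CRM
      d <- pmax(0L, pmax(cr$start - t - 1L, t - cr$end))
      keep <- which(d < window)
      if (!length(keep)) return(NULL)
      nearest <- ifelse(cr$start[keep] > t, cr$start[keep],
                        ifelse(t > cr$end[keep] - 1L, cr$end[keep] - 1L, t))
      lo <- pmin(t, nearest); hi <- pmax(t, nearest)
      nins <- if (length(mids))
        vapply(seq_along(keep), function(m)
          sum(mids > lo[m] & mids < hi[m]), integer(1L))
      else rep(0L, length(keep))
      data.frame(crm_id = cr$crm_id[keep], gene_id = g$gene_id[k],
                 distance = d[keep], insulator_count = nins,
                 stringsAsFactors = FALSE)
    })
    out[[ci]] <- do.call(rbind, res)
  }
  lt <- do.call(rbind, out)
  if (is.null(lt))
    lt <- data.frame(crm_id = character(), gene_id = character(),
                     distance = numeric(), insulator_count = integer(),
                     stringsAsFactors = FALSE)
  rownames(lt) <- NULL
  class(lt) <- c("link_table", "data.frame")
  lt
}

#' Read/write a link table as TSV
#' @param path TSV path with columns crm_id, gene_id, distance,
#'   insulator_count.
#' @export
read_link_table <- function(path) {
  lt <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("crm_id", "gene_id", "distance", "insulator_count")
                %in% names(lt)))
  class(lt) <- c("link_table", "data.frame")
  lt
}

#' @rdname read_link_table
#' @param lt link table.
#' @export
write_link_table <- function(lt, path) {
  write.table(lt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average and discretize promoter H3K4me3 signal
#'
#' For each gene the processed signal is averaged over the strand-oriented
#' promoter window \[TSS-up, TSS+down) (bases without coverage count as 0)
#' and called high when the mean reaches `threshold`.  Each signal track
#' corresponds to one developmental time window; the `window_class_map`
#' assigns temporal activity classes to tracks, and spatial classes take
#' the union (high in any track).  The promoter response is
#' `p_high`/`p_low` for high/low promoters.
#'
#' @param tracks named list, one element per time window, each a data.frame
#'   with columns `chrom`, `start`, `end` (0-based half-open), `value` (a
#'   bedGraph), or a path to a bedGraph file.
#' @param layout a `genome_layout`.
#' @param up,down bp upstream / downstream of the TSS (defaults 100 / 400).
#' @param threshold high/low cutoff on the window mean (default 0.3; the
#'   signal units are those of the processed track).
#' @param classes data.frame with columns `name`, `axis`
#'   (`"spatial"`/`"temporal"`); default [default_classes()].
#' @param window_class_map data.frame with columns `class`, `window`
#'   mapping temporal class names to track names; default maps the five
#'   canonical stage classes onto 4-8 h / 8-12 h / 12-16 h tracks.
#' @param p_high,p_low promoter response for high / low promoters.
#' @return object of class `promoter_activity`: list with `mean` (gene x
#'   track matrix), `high` (logical gene x track), `R` (gene x class matrix
#'   of responses in \[0,1\]), `uncovered` (gene ids with no coverage in
#'   some track).
#' @export
discretize_promoter_signal <- function(tracks, layout, up = 100, down = 400,
                                       threshold = 0.3,
                                       classes = default_classes(),
                                       window_class_map = NULL,
                                       p_high = 0.95, p_low = 0.05) {
  stopifnot(inherits(layout, "genome_layout"))
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop("tracks must be a named list (one name per time window)")
  tss <- layout$tss
  width <- up + down
  means <- matrix(0, nrow(tss), length(tracks),
                  dimnames = list(tss$gene_id, names(tracks)))
  uncovered <- character(0)
  t0 <- tss$pos - 1L
  wlo <- ifelse(tss$strand == "+", t0 - up, t0 - down + 1L)
  whi <- wlo + width                      # [wlo, whi)
  for (tn in names(tracks)) {
    tr <- tracks[[tn]]
    if (is.character(tr)) tr <- read_bedgraph(tr)
    stopifnot(all(c("chrom", "start", "end", "value") %in% names(tr)))
    for (ch in unique(tss$chrom)) {
      gi <- which(tss$chrom == ch)
      seg <- tr[tr$chrom == ch, , drop = FALSE]
      if (!nrow(seg)) { uncovered <- c(uncovered, tss$gene_id[gi]); next }
      segr <- IRanges::IRanges(seg$start + 1L, seg$end)   # 1-based closed
      winr <- IRanges::IRanges(wlo[gi] + 1L, whi[gi])
      ov <- IRanges::findOverlaps(winr, segr)
      olap <- IRanges::width(IRanges::pintersect(
        winr[S4Vectors::queryHits(ov)], segr[S4Vectors::subjectHits(ov)]))
      contrib <- olap * seg$value[S4Vectors::subjectHits(ov)]
      s <- rowsum(contrib, group = S4Vectors::queryHits(ov))
      idx <- as.integer(rownames(s))
      means[gi[idx], tn] <- s[, 1L] / width
      nohit <- setdiff(seq_along(gi), idx)
      if (length(nohit)) uncovered <- c(uncovered, tss$gene_id[gi[nohit]])
    }
  }
  if (length(uncovered))
    message(length(unique(uncovered)),
            " gene(s) without track coverage; mean set to 0")
  high <- means >= threshold
  if (is.null(window_class_map))
    window_class_map <- default_window_class_map(names(tracks))
  R <- matrix(NA_real_, nrow(tss), nrow(classes),
              dimnames = list(tss$gene_id, classes$name))
  any_high <- apply(high, 1L, any)
  for (k in seq_len(nrow(classes))) {
    cl <- classes$name[k]
    if (classes$axis[k] == "spatial") {
      h <- any_high
    } else {
      w <- window_class_map$window[window_class_map$class == cl]
      if (!length(w) || !w %in% colnames(high))
        stop("temporal class '", cl, "' has no mapped signal track")
      h <- high[, w]
    }
    R[, k] <- ifelse(h, p_high, p_low)
  }
  structure(list(mean = means, high = high, R = R,
                 uncovered = unique(uncovered)),
            class = "promoter_activity")
}

#' Canonical activity classes
#'
#' Five tissue (spatial) classes and five developmental stage (temporal)
#' classes used throughout: mesoderm (meso), somatic muscle (sm), visceral
#' muscle (vm), the two compound tissue classes, and stage windows 4-6,
#' 7-8, 9-10, 11-12, 13-16.
#' @return data.frame with columns `name`, `axis`.
#' @export
default_classes <- function() {
  data.frame(
    name = c("meso", "sm", "vm", "meso_sm", "sm_vm",
             "st4-6", "st7-8", "st9-10", "st11-12", "st13-16"),
    axis = rep(c("spatial", "temporal"), each = 5L),
    stringsAsFactors = FALSE)
}

# default mapping of stage classes onto the three H3K4me3 time windows
default_window_class_map <- function(track_names) {
  std <- c("st4-6" = "4-8h", "st7-8" = "4-8h", "st9-10" = "8-12h",
           "st11-12" = "8-12h", "st13-16" = "12-16h")
  if (all(std %in% track_names))
    return(data.frame(class = names(std), window = unname(std),
                      stringsAsFactors = FALSE))
  if (length(track_names) == 1L)
    return(data.frame(class = names(std), window = track_names,
                      stringsAsFactors = FALSE))
  stop("supply window_class_map: tracks ",
       paste(track_names, collapse = ","),
       " do not match the default 4-8h/8-12h/12-16h windows")
}

#' Read/write bedGraph tracks (0-based half-open)
#' @param path bedGraph file (4 columns, no header; `track` lines skipped).
#' @return data.frame with columns chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^(track|#|browser)", ln) & nzchar(ln)]
  df <- read.delim(text = paste(ln, collapse = "\n"), header = FALSE,
                   stringsAsFactors = FALSE)
  stats::setNames(df[, 1:4], c("chrom", "start", "end", "value"))
}

#' @rdname read_bedgraph
#' @param track data.frame with chrom, start, end, value.
#' @export
write_bedgraph <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Map anatomical annotation terms to binary class labels
#'
#' A gene is labeled active in a class iff at least one of its terms maps
#' to it; genes carrying any excluded term (ubiquitous / maternal patterns)
#' are dropped entirely.  Genes present in the annotation but with no term
#' for a class are labeled inactive for that class (absence of the term in
#' an annotated gene is negative evidence; genes absent from the table are
#' simply unlabeled).
#'
#' @param raw_terms data.frame with columns `gene_id`, `term`.
#' @param mapping data.frame with columns `term`, `class`.
#' @param exclude character vector of terms that disqualify a gene.
#' @param classes class table as in [default_classes()].
#' @return a `label_table` data.frame: `entity_id`, `class`, `label` (0/1).
#' @export
map_annotation_terms <- function(raw_terms, mapping,
                                 exclude = c("ubiquitous", "maternal"),
                                 classes = default_classes()) {
  stopifnot(all(c("gene_id", "term") %in% names(raw_terms)),
            all(c("term", "class") %in% names(mapping)))
  drop <- unique(raw_terms$gene_id[raw_terms$term %in% exclude])
  terms <- raw_terms[!raw_terms$gene_id %in% drop, , drop = FALSE]
  unknown <- setdiff(unique(terms$term), c(mapping$term, exclude))
  if (length(unknown))
    warning("ignoring unmapped term(s): ", paste(unknown, collapse = ", "))
  genes <- unique(terms$gene_id)
  if (!length(genes))
    return(label_table(character(), character(), integer()))
  hit <- merge(terms, mapping, by = "term")
  rows <- expand.grid(entity_id = genes, class = classes$name,
                      stringsAsFactors = FALSE)
  key <- paste(hit$gene_id, hit$class)
  rows$label <- as.integer(paste(rows$entity_id, rows$class) %in% key)
  label_table(rows$entity_id, rows$class, rows$label)
}

#' Construct or read a label table
#'
#' Long-format binary activity labels for CRMs or genes.
#' @param entity_id,class,label parallel vectors.
#' @return data.frame of class `label_table`.
#' @export
label_table <- function(entity_id, class, label) {
  stopifnot(all(label %in% c(0L, 1L)))
  df <- data.frame(entity_id = as.character(entity_id),
                   class = as.character(class),
                   label = as.integer(label), stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("entity_id", "class")]))
    stop("duplicated (entity_id, class) in label table")
  class(df) <- c("label_table", "data.frame")
  df
}

#' @rdname label_table
#' @param path TSV with columns entity_id, class, label.
#' @export
read_label_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  label_table(df$entity_id, df$class, df$label)
}

#' @rdname label_table
#' @param x a label table.
#' @export
write_label_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# label_table -> entity x class matrix (NA = unlabeled)
label_matrix <- function(labels, entities, classes) {
  m <- matrix(NA_real_, length(entities), length(classes),
              dimnames = list(entities, classes))
  keep <- labels$entity_id %in% entities & labels$class %in% classes
  l <- labels[keep, , drop = FALSE]
  m[cbind(match(l$entity_id, entities), match(l$class, classes))] <- l$label
  m
}
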