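# Seeded generative simulator: a linear genome with genes, CRMs and
# insulator peaks, occupancy drawn from per-variable bound/unbound
# mixtures, latent CRM activity from a planted bipartite network, and
# expression sampled from the noisy-OR gene model.

#' Build a simulation configuration
#'
#' Defaults describe the "desk" world used throughout the test suite; see
#' the methods vignette for the rationale behind each constant.
#'
#' @param n_genes,n_crms,n_insulator_peaks entity counts.
#' @param chrom_length chromosome length in bp (default `n_genes * 8000`:
#'   one gene per ~8 kb).
#' @param binding_vars names of the TF/time binding variables.
#' @param classes class table as in [default_classes()].
#' @param parent_sets named list: class name -> character vector of parent
#'   binding variables (the planted structure); `NULL` for the default
#'   1-2-parent assignment.
#' @param cpt_noise planted CPT end-point noise: `P(active | config) =
#'   cpt_noise + (1 - 2*cpt_noise) * (bound parents / parents)` (default
#'   0.1).
#' @param true_dmax planted maximal distance (default 20 kb).
#' @param insulator_limit blocking threshold (default 0).
#' @param mix_unbound,mix_bound `c(mean, sd)` of the unbound / bound
#'   occupancy components (signal truncated at 0).
#' @param bound_fraction marginal probability a binding variable is bound.
#' @param p_high,p_low promoter responses; `prob_promoter_high` marginal
#'   probability of a high promoter call per gene and time window.
#' @param reveal_crm_fraction,reveal_gene_fraction fractions of CRMs /
#'   genes whose true activity / expression labels are revealed.
#' @param window link-window limit in bp.
#' @param seed integer seed; the whole bundle is a pure function of the
#'   config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1500L, n_crms = 800L,
                       n_insulator_peaks = NULL,
                       chrom_length = NULL,
                       binding_vars = default_binding_vars(),
                       classes = default_classes(),
                       parent_sets = NULL,
                       cpt_noise = 0.1,
                       true_dmax = 20000,
                       insulator_limit = 0L,
                       mix_unbound = c(1, 0.5), mix_bound = c(3, 0.7),
                       bound_fraction = 0.3,
                       p_high = 0.95, p_low = 0.05,
                       prob_promoter_high = 0.7,
                       reveal_crm_fraction = 0.04,
                       reveal_gene_fraction = 0.35,
                       window = 1e5, seed = 1L) {
  if (is.null(chrom_length)) chrom_length <- n_genes * 8000
  if (is.null(n_insulator_peaks))
    n_insulator_peaks <- round(chrom_length / 25000)
  if (is.null(parent_sets)) parent_sets <-
      default_parent_sets(binding_vars, classes$name)
  stopifnot(all(unlist(parent_sets) %in% binding_vars),
            all(names(parent_sets) %in% classes$name),
            cpt_noise >= 0, cpt_noise < 0.5,
            true_dmax > 0, true_dmax <= window,
            reveal_crm_fraction >= 0, reveal_crm_fraction <= 1,
            reveal_gene_fraction >= 0, reveal_gene_fraction <= 1)
  structure(list(n_genes = as.integer(n_genes), n_crms = as.integer(n_crms),
                 n_insulator_peaks = as.integer(n_insulator_peaks),
                 chrom_length = chrom_length, binding_vars = binding_vars,
                 classes = classes, parent_sets = parent_sets,
                 cpt_noise = cpt_noise, true_dmax = true_dmax,
                 insulator_limit = as.integer(insulator_limit),
                 mix_unbound = mix_unbound, mix_bound = mix_bound,
                 bound_fraction = bound_fraction,
                 p_high = p_high, p_low = p_low,
                 prob_promoter_high = prob_promoter_high,
                 reveal_crm_fraction = reveal_crm_fraction,
                 reveal_gene_fraction = reveal_gene_fraction,
                 window = window, seed = as.integer(seed)),
            class = "sim_config")
}

#' Canonical binding-variable names (5 TFs x 3 time points)
#' @export
default_binding_vars <- function() {
  as.vector(outer(c("twi", "tin", "mef2", "bin", "bap"),
                  c("2-4h", "4-6h", "6-8h"), paste, sep = "_"))
}

# fixed planted structure: each class depends on 1-2 binding variables
default_parent_sets <- function(vars, class_names) {
  sets <- list(
    c(vars[1L]),             # meso      <- twi_2-4h
    c(vars[3L], vars[8L]),   # sm        <- mef2_2-4h, mef2_4-6h
    c(vars[9L], vars[14L]),  # vm        <- bin_4-6h, bin_6-8h
    c(vars[1L], vars[3L]),   # meso_sm   <- twi_2-4h, mef2_2-4h
    c(vars[8L], vars[9L]),   # sm_vm     <- mef2_4-6h, bin_4-6h
    c(vars[2L]),             # st4-6     <- tin_2-4h
    c(vars[6L]),             # st7-8     <- twi_4-6h
    c(vars[7L]),             # st9-10    <- tin_4-6h
    c(vars[12L]),            # st11-12   <- tin_6-8h
    c(vars[13L], vars[15L])) # st13-16   <- mef2_6-8h, bap_6-8h
  stats::setNames(sets[seq_along(class_names)], class_names)
}

# planted CPT over configurations of |parents| bits (low bit = parent 1)
planted_cpt <- function(n_parents, noise) {
  if (n_parents == 0L) return(0.5)
  cfg <- seq_len(2^n_parents) - 1L
  nbits <- vapply(cfg, function(x) sum(bitwAnd(x, 2^(0:30)) > 0), numeric(1))
  noise + (1 - 2 * noise) * nbits / n_parents
}

#' Generate a complete synthetic dataset bundle
#'
#' Genomic placement is uniform; binding states, occupancy, latent CRM
#' activity, promoter states and expression labels are sampled from the
#' model's own generative assumptions; labels are then masked down to the
#' revealed fractions.  The bundle is bitwise reproducible from the config.
#'
#' @param config a `sim_config`.
#' @return list of class `sim_bundle` with elements `occupancy`, `layout`
#'   (a `genome_layout`), `links`, `R` (gene x class responses),
#'   `promoter_high` (gene x window logical), `crm_labels`, `gene_labels`
#'   (revealed `label_table`s), `truth` (list: `activity`, `expression`,
#'   `binding_states`, `bn`, `dmax`, `p_expressed`), and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cl_names <- config$classes$name
  nv <- length(config$binding_vars)
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  crm_ids <- sprintf("crm%04d", seq_len(config$n_crms))
  # (1) genomic placement: uniform with a minimum gap, so CRMs never
  # overlap (they are non-overlapping by construction in the real data)
  # and promoter windows of neighboring genes stay disjoint
  place <- function(n, length, gap, margin = 0L) {
    stopifnot(length > 2L * margin + n * gap)
    sort(sample.int(length - 2L * margin - (n - 1L) * gap, n)) +
      margin + (seq_len(n) - 1L) * gap
  }
  tss_pos <- place(config$n_genes, config$chrom_length, 1100L, 600L)
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  crm_start <- place(config$n_crms, config$chrom_length, 650L)
  crm_len <- sample(200:600, config$n_crms, replace = TRUE)
  ins_start <- if (config$n_insulator_peaks > 0)
    place(config$n_insulator_peaks, config$chrom_length, 250L)
  else integer(0)
  layout <- genome_layout(
    tss = data.frame(gene_id = gene_ids, chrom = "chr2L", pos = tss_pos,
                     strand = strand, stringsAsFactors = FALSE),
    crms = data.frame(crm_id = crm_ids, chrom = "chr2L", start = crm_start,
                      end = pmin(crm_start + crm_len, config$chrom_length),
                      stringsAsFactors = FALSE),
    insulators = if (config$n_insulator_peaks > 0)
      data.frame(chrom = "chr2L", start = ins_start,
                 end = ins_start + 200L, stringsAsFactors = FALSE)
    else data.frame(chrom = character(), start = integer(),
                    end = integer(), stringsAsFactors = FALSE))
  # (2) binding states and continuous occupancy
  B <- matrix(rbinom(config$n_crms * nv, 1L, config$bound_fraction),
              config$n_crms, nv,
              dimnames = list(crm_ids, config$binding_vars))
  occ <- matrix(rnorm(config$n_crms * nv,
                      ifelse(B == 1L, config$mix_bound[1L],
                             config$mix_unbound[1L]),
                      ifelse(B == 1L, config$mix_bound[2L],
                             config$mix_unbound[2L])),
                config$n_crms, nv,
                dimnames = list(crm_ids, config$binding_vars))
  occ <- pmax(occ, 0)
  class(occ) <- c("occupancy_matrix", class(occ))
  # (3) latent CRM activity from the planted network
  bn <- planted_bn(config)
  activity <- matrix(0L, config$n_crms, length(cl_names),
                     dimnames = list(crm_ids, cl_names))
  for (cl in cl_names) {
    par <- bn$nodes[[cl]]$parents
    cpt <- bn$nodes[[cl]]$cpt
    cfg <- if (length(par))
      as.vector(B[, par, drop = FALSE] %*% 2^(seq_along(par) - 1L)) + 1L
    else rep(1L, config$n_crms)
    activity[, cl] <- rbinom(config$n_crms, 1L, cpt[cfg])
  }
  # (4) promoter states per time window -> responses per class
  windows <- c("4-8h", "8-12h", "12-16h")
  ph <- matrix(rbinom(config$n_genes * length(windows), 1L,
                      config$prob_promoter_high) == 1L,
               config$n_genes, length(windows),
               dimnames = list(gene_ids, windows))
  map <- default_window_class_map(windows)
  R <- matrix(NA_real_, config$n_genes, length(cl_names),
              dimnames = list(gene_ids, cl_names))
  any_high <- apply(ph, 1L, any)
  for (k in seq_len(nrow(config$classes))) {
    cl <- cl_names[k]
    h <- if (config$classes$axis[k] == "spatial") any_high
         else ph[, map$window[map$class == cl]]
    R[, k] <- promoter_response(h, config$p_high, config$p_low)
  }
  # (5) expression sampled from the noisy-OR activation probability
  links <- build_link_table(layout, config$window)
  p_exp <- activation_matrix(links, activity, R, config$true_dmax,
                             config$insulator_limit)
  expression <- matrix(rbinom(length(p_exp), 1L, as.vector(p_exp)),
                       nrow(p_exp), ncol(p_exp), dimnames = dimnames(p_exp))
  prev <- colMeans(expression)
  if (any(prev == 0))
    warning("class(es) with zero sampled positives: ",
            paste(cl_names[prev == 0], collapse = ", "))
  # (6) mask labels down to the revealed fractions
  n_rev_crm <- round(config$reveal_crm_fraction * config$n_crms)
  n_rev_gene <- round(config$reveal_gene_fraction * config$n_genes)
  rev_crms <- sort(sample(crm_ids, n_rev_crm))
  rev_genes <- sort(sample(gene_ids, n_rev_gene))
  crm_labels <- label_table(
    rep(rev_crms, times = length(cl_names)),
    rep(cl_names, each = length(rev_crms)),
    as.integer(activity[rev_crms, ]))
  gene_labels <- label_table(
    rep(rev_genes, times = length(cl_names)),
    rep(cl_names, each = length(rev_genes)),
    as.integer(expression[rev_genes, ]))
  structure(list(occupancy = occ, layout = layout, links = links, R = R,
                 promoter_high = ph, crm_labels = crm_labels,
                 gene_labels = gene_labels,
                 truth = list(activity = activity, expression = expression,
                              binding_states = B, bn = bn,
                              dmax = config$true_dmax, p_expressed = p_exp),
                 config = config),
            class = "sim_bundle")
}

# the planted network as a bipartite_bn object (comparable to learned ones)
planted_bn <- function(config) {
  nodes <- lapply(config$classes$name, function(cl) {
    par <- config$parent_sets[[cl]]
    if (is.null(par)) par <- character(0)
    list(parents = par, cpt = planted_cpt(length(par), config$cpt_noise))
  })
  names(nodes) <- config$classes$name
  structure(list(nodes = nodes, binding_vars = config$binding_vars,
                 ess = 1, max_parents = 3L), class = "bipartite_bn")
}

#' Ready-made paper-scale and desk-scale configurations
#'
#' `"paper"` approximates the real data's dimensions (~8000 CRMs, ~15000
#' genes of which ~1/3 have revealed expression); `"desk"` is the ~1/10
#' world the test suite runs on.
#'
#' @param scale `"desk"` (default) or `"paper"`.
#' @param seed seed stored in the config.
#' @return a `sim_config`.
#' @export
default_paper_scale <- function(scale = c("desk", "paper"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "paper")
    sim_config(n_genes = 15000L, n_crms = 8000L, seed = seed)
  else
    sim_config(n_genes = 1500L, n_crms = 800L, seed = seed)
}

#' Write a simulated bundle to standard files
#'
#' Emits exactly the formats the readers consume: occupancy TSV, gene
#' models GFF3, CRM and insulator BED, promoter-state bedGraph per time
#' window, link-table TSV and revealed label TSVs.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_occupancy(bundle$occupancy, p("occupancy.tsv"))
  lay <- bundle$layout
  gr <- GenomicRanges::GRanges(
    lay$tss$chrom,
    IRanges::IRanges(lay$tss$pos, lay$tss$pos), strand = lay$tss$strand,
    type = "gene", ID = lay$tss$gene_id)
  rtracklayer::export(gr, p("genes.gff3"), format = "gff3")
  crm_gr <- GenomicRanges::GRanges(
    lay$crms$chrom, IRanges::IRanges(lay$crms$start + 1L, lay$crms$end),
    name = lay$crms$crm_id)
  rtracklayer::export(crm_gr, p("crms.bed"), format = "bed")
  if (nrow(lay$insulators)) {
    ins_gr <- GenomicRanges::GRanges(
      lay$insulators$chrom,
      IRanges::IRanges(lay$insulators$start + 1L, lay$insulators$end))
    rtracklayer::export(ins_gr, p("insulators.bed"), format = "bed")
  }
  # promoter state as a bedGraph per time window: 1 over the promoter
  # window of high genes (recovers the same calls at threshold 0.3)
  t0 <- lay$tss$pos - 1L
  wlo <- ifelse(lay$tss$strand == "+", t0 - 100L, t0 - 400L + 1L)
  for (w in colnames(bundle$promoter_high)) {
    hi <- bundle$promoter_high[, w]
    write_bedgraph(
      data.frame(chrom = lay$tss$chrom[hi], start = pmax(wlo[hi], 0L),
                 end = pmax(wlo[hi], 0L) + 500L, value = 1),
      p(paste0("h3k4me3_", w, ".bedgraph")))
  }
  write_link_table(bundle$links, p("links.tsv"))
  write_label_table(bundle$crm_labels, p("crm_labels.tsv"))
  write_label_table(bundle$gene_labels, p("gene_labels.tsv"))
  invisible(dir)
}
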