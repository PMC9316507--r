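fixture_path <- function(name) {
  system.file("extdata", name, package = "circaid", mustWork = TRUE)
}

#' Load the packaged circRNA inventory fixture
#'
#' A nine-row inventory of full-length circRNAs of one gene (id,
#' GenBank-style accession, sample label, exon count, exon list with
#' truncation asterisks, length in nt), packaged as a worked example for
#' the catalog summariser. Integrity is asserted at load: nine rows, a
#' contiguous accession range, and an exon count that equals the length
#' of each row's exon list.
#'
#' @return data.frame with columns `circ_id`, `accession`, `cell_lines`,
#'   `exon_count`, `exons`, `length`.
#' @export
table1_fixture <- function() {
  t1 <- utils::read.table(fixture_path("table1_circrnas.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          quote = "")
  if (nrow(t1) != 9L) stop("inventory fixture must have 9 rows",
                           call. = FALSE)
  expected_acc <- sprintf("ON0810%d", 37:45)
  if (!identical(t1$accession, expected_acc)) {
    stop("accession range corrupted", call. = FALSE)
  }
  n_listed <- lengths(strsplit(t1$exons, ","))
  if (!identical(as.integer(t1$exon_count), as.integer(n_listed))) {
    stop("exon_count disagrees with exon list", call. = FALSE)
  }
  t1
}

#' Load the packaged miRNA prediction fixture
#'
#' For each circRNA of the inventory, the two top-scoring predicted
#' miRNA interactions (score scale up to 100) with the binding motif as
#' printed on the target strand.
#'
#' @return data.frame with columns `circ_id`, `mirna_id`,
#'   `prediction_score`, `motif`.
#' @export
table2_fixture <- function() {
  t2 <- utils::read.table(fixture_path("table2_mirna.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          quote = "")
  per_circ <- table(t2$circ_id)
  if (any(per_circ != 2L)) {
    stop("expected two miRNA rows per circRNA", call. = FALSE)
  }
  if (any(t2$prediction_score > 100)) {
    stop("prediction scores exceed the 0-100 scale", call. = FALSE)
  }
  t2
}

#' Load the packaged m6A context fixture
#'
#' Printed m6A site contexts (9-mers centred on the modified A) of the
#' ORF-bearing circRNAs in the packaged inventory.
#'
#' @return data.frame with columns `circ_id`, `position`, `context_9mer`,
#'   `score`.
#' @export
table4_fixture <- function() {
  utils::read.table(fixture_path("table4_m6a.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE, quote = "")
}

# parse "Exon 3 *, Exon 4" -> integer exon indices
parse_exon_list <- function(x) {
  lapply(strsplit(x, ","), function(parts) {
    as.integer(sub("^\\s*Exon\\s+(\\d+).*$", "\\1", parts))
  })
}

#' Summarise a circRNA catalog or inventory
#'
#' Deterministic summary of a catalog (from [dedupe_and_catalog()]) or
#' of the packaged inventory fixture: number of circles, how many
#' circles contain each exon (each circle counts once per exon index),
#' the most frequent exon, and the length range.
#'
#' @param catalog data.frame with columns `exons` (exon list string) and
#'   `length`.
#' @return list: `n_circrnas`, `exon_counts` (named integer vector),
#'   `most_frequent_exon`, `min_length`, `max_length`.
#' @export
summarize_catalog <- function(catalog) {
  if (!is.data.frame(catalog) || nrow(catalog) == 0L) {
    stop("empty catalog", call. = FALSE)
  }
  ex <- parse_exon_list(catalog$exons)
  counts <- table(unlist(lapply(ex, unique)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(n_circrnas = nrow(catalog),
       exon_counts = counts,
       most_frequent_exon = as.integer(names(counts)[which.max(counts)]),
       min_length = min(catalog$length),
       max_length = max(catalog$length))
}

#' Summarise a top-miRNA prediction table
#'
#' Counts, for each miRNA, how many distinct circRNAs list it among
#' their top-scoring predicted interactions.
#'
#' @param t2 data.frame with columns `circ_id` and `mirna_id`.
#' @return named integer vector (miRNA -> number of circRNAs), sorted
#'   decreasingly.
#' @export
summarize_mirna_table <- function(t2) {
  if (nrow(t2) == 0L) return(stats::setNames(integer(0), character(0)))
  counts <- vapply(split(t2$circ_id, t2$mirna_id),
                   function(x) length(unique(x)), integer(1))
  sort(counts, decreasing = TRUE)
}

pipeline_log <- function(log_lines, path = NULL) {
  if (!is.null(path)) writeLines(log_lines, path)
  invisible(log_lines)
}

#' Run the full discovery pipeline
#'
#' Executes simulate (or load) -> annotate -> confirm -> dedupe ->
#' features -> report, logging counts in and out of every stage. The
#' configuration is a nested list (or a YAML file path) with blocks:
#' \describe{
#'   \item{`simulate`}{`n_circles`, `n_reads_per_circle`, plus any
#'     [sim_config()] argument — used when no read FASTA is given;}
#'   \item{`inputs`}{`bed`, `fasta`, `reads` (FASTA paths) for real
#'     data;}
#'   \item{`features`}{optional `mirna_fasta`, `rbp_motifs` (TSV with
#'     columns rbp, pattern);}
#'   \item{`primers`}{optional `exon` (target exon index) to design
#'     first-round and nested divergent pairs;}
#'   \item{`out_dir`}{output directory for catalog.tsv, features.json,
#'     primers.tsv, rejected.log, pipeline.log.}
#' }
#'
#' @param config nested list or YAML path.
#' @return (invisibly) list: `status` (0 on success, 1 when no circRNA
#'   was confirmed), `catalog`, `circs`, `features`, `rejections`,
#'   `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  truths <- NULL
  if (!is.null(config$inputs)) {
    for (key in c("bed", "fasta", "reads")) {
      if (is.null(config$inputs[[key]])) {
        stop("config key inputs$", key, " is required for real input",
             call. = FALSE)
      }
    }
    model <- load_gene_model(config$inputs$bed, config$inputs$fasta)
    reads <- read_fasta(config$inputs$reads)
    say("loaded gene model '", model$gene_id, "' with ", n_exons(model),
        " exons; ", length(reads), " reads")
  } else if (!is.null(config$simulate)) {
    simblock <- config$simulate
    n_circles <- simblock$n_circles %||% 5L
    n_reads <- simblock$n_reads_per_circle %||% 10L
    cfg_args <- simblock[setdiff(names(simblock),
                                 c("n_circles", "n_reads_per_circle"))]
    base_cfg <- do.call(sim_config, cfg_args)
    model <- simulate_gene(base_cfg)
    say("simulated gene with ", n_exons(model), " exons (seed ",
        base_cfg$seed, ")")
    # plant circles sequentially on the evolving locus, then rebuild all
    # circle sequences against the final model so every read is
    # consistent with the locus used for annotation
    sims <- list()
    for (i in seq_len(n_circles)) {
      cfg_i <- base_cfg
      cfg_i$seed <- base_cfg$seed + 101L * i
      sims[[i]] <- simulate_circrna(model, cfg_i)
      model <- sims[[i]]$model
    }
    reads <- character(0)
    truths <- lapply(sims, `[[`, "truth")
    for (i in seq_len(n_circles)) {
      circ <- rebuild_circ(sims[[i]]$circ, model)
      cfg_i <- base_cfg
      cfg_i$seed <- base_cfg$seed + 101L * i + 1L
      ri <- simulate_reads(circ, n_reads, cfg_i)
      names(ri) <- paste0("circ", i, "_", names(ri))
      reads <- c(reads, ri)
    }
    say("simulated ", n_circles, " circles, ", length(reads), " reads")
  } else {
    stop("config needs either an 'inputs' or a 'simulate' block",
         call. = FALSE)
  }

  params <- do.call(annot_params, config$annotate %||% list())
  index <- build_exon_index(model, params$min_anchor)
  results <- lapply(seq_along(reads), function(i) {
    annotate_read(reads[[i]], model, params, index,
                  read_id = names(reads)[i] %||% paste0("read", i))
  })
  say("annotated ", length(results), " reads; ",
      sum(vapply(results, function(r) !is.null(r$bsj), logical(1))),
      " with a BSJ call")

  confirmed <- list()
  rejections <- list()
  for (r in results) {
    cc <- confirm_and_reconstruct(r, model, params)
    if (inherits(cc, "circ_rna")) confirmed[[length(confirmed) + 1L]] <- cc
    else rejections[[length(rejections) + 1L]] <- cc
  }
  say("confirmed ", length(confirmed), " reads; rejected ",
      length(rejections))

  dd <- dedupe_and_catalog(confirmed)
  say("catalog: ", nrow(dd$catalog), " distinct circRNAs")

  mirnas <- config$features$mirna_fasta
  rbp <- config$features$rbp_motifs
  if (!is.null(rbp) && is.character(rbp)) {
    rbp <- utils::read.table(rbp, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  }
  feats <- if (nrow(dd$catalog) > 0L) {
    circ_features(dd$circs, mirnas = mirnas, rbp_motifs = rbp)
  }

  pairs <- NULL
  if (!is.null(config$primers$exon)) {
    pairs <- tryCatch({
      first <- design_divergent_pair(model, config$primers$exon)
      nested <- design_second_round(first, model, "nested")
      say("designed divergent pair + nested pair on exon ",
          config$primers$exon)
      list(first, nested)
    }, error = function(e) {
      say("primer design on exon ", config$primers$exon, " failed: ",
          conditionMessage(e))
      NULL
    })
  }

  if (!is.null(out_dir)) {
    write_catalog(dd$catalog, file.path(out_dir, "catalog.tsv"))
    if (!is.null(feats)) {
      jsonlite::write_json(feats, file.path(out_dir, "features.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
    if (!is.null(pairs)) {
      write_primer_table(pairs, file.path(out_dir, "primers.tsv"))
    }
    writeLines(vapply(rejections, function(x) {
      paste0(x$read_id, "\t", x$reason)
    }, character(1)), file.path(out_dir, "rejected.log"))
    pipeline_log(log_lines, file.path(out_dir, "pipeline.log"))
  }
  status <- if (nrow(dd$catalog) == 0L) 1L else 0L
  if (status != 0L) say("no circRNA confirmed: empty catalog")
  invisible(list(status = status, catalog = dd$catalog, circs = dd$circs,
                 features = feats, primers = pairs, truths = truths,
                 rejections = rejections, log = log_lines))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# recut a circle's sequence and junction flags against a (possibly
# edited) model, keeping its segment structure
rebuild_circ <- function(circ, model) {
  segments <- circ$segments
  seq <- paste(vapply(seq_len(nrow(segments)), function(j) {
    substr(exon_seq(model, segments$exon_index[j]),
           segments$seg_start[j] + 1L, segments$seg_end[j])
  }, character(1)), collapse = "")
  bsj <- annotate_bsj_flags(circ$bsj, model)
  circ_rna(circ$id, segments, seq, bsj, support = circ$support,
           sample = circ$sample)
}
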