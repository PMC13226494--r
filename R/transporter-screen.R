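#' Read tabular transporter-survey inputs
#'
#' The screening module works on plain TSV exports of the bioinformatic
#' survey: homology hits against transporter references, membrane-topology
#' predictions, signal-peptide calls, and operon composition records. These
#' readers validate the schemas.
#'
#' * hits: `query_id`, `subject_id`, `bit_score`, `family_hint`
#'   (one of MFS, NCS1, ABC_TM, ABC_SBP, ABC_NBP, PTS), `genome`, optional
#'   `substrate`.
#' * topology: `seq_id`, `tm_helix_count`, `has_signal_peptide`, `length_aa`.
#' * operons: `operon_id`, `seq_id`, `role` (SBP, NBP, TM, or EII for
#'   phosphotransferase components), `genome`, optional `substrate`.
#' * scores: `query_id`, `subject_id`, `bit_score` (for best-hit analysis).
#'
#' @param path TSV file path.
#' @return A tibble with validated columns.
#' @export
read_hit_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need_cols(x, c("query_id", "subject_id", "bit_score", "family_hint",
                 "genome"), "hit table")
  bad <- setdiff(unique(x$family_hint), transporter_families())
  if (length(bad) > 0) {
    abort(paste0("unknown family_hint value(s): ", paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(x$bit_score))) abort("bit scores must be finite.")
  x
}

#' @rdname read_hit_table
#' @export
read_topology_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need_cols(x, c("seq_id", "tm_helix_count", "has_signal_peptide",
                 "length_aa"), "topology table")
  if (any(x$tm_helix_count < 0)) abort("tm_helix_count must be >= 0.")
  x$has_signal_peptide <- as.logical(x$has_signal_peptide)
  x
}

#' @rdname read_hit_table
#' @export
read_operon_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need_cols(x, c("operon_id", "seq_id", "role", "genome"), "operon table")
  bad <- setdiff(unique(x$role), c("SBP", "NBP", "TM", "EII"))
  if (length(bad) > 0) {
    abort(paste0("unknown operon role(s): ", paste(bad, collapse = ", ")))
  }
  if (!"substrate" %in% names(x)) x$substrate <- NA_character_
  x
}

#' @rdname read_hit_table
#' @export
read_score_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need_cols(x, c("query_id", "subject_id", "bit_score"), "score table")
  x
}

need_cols <- function(x, cols, what) {
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(what, " lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  invisible(x)
}

transporter_families <- function() {
  c("MFS", "NCS1", "ABC_TM", "ABC_SBP", "ABC_NBP", "PTS")
}

#' Retain homology hits above a bit-score threshold
#'
#' Strictly-greater-than comparison: a hit scoring exactly the threshold is
#' rejected.
#'
#' @param hits Hit tibble (see [read_hit_table()]).
#' @param threshold Bit-score threshold (default 100).
#' @return The retained subset of `hits`.
#' @export
filter_by_bitscore <- function(hits, threshold = 100) {
  stopifnot(is.data.frame(hits))
  need_cols(hits, "bit_score", "hit table")
  dplyr::filter(hits, .data$bit_score > threshold)
}

#' Retain sequences with the family's expected membrane topology
#'
#' Single-gene secondary transporters of the MFS and NCS-1 families are
#' expected to span the membrane with 12 alpha-helices; transmembrane
#' subunits of ABC importers with 3 or 6. Sequences with any other predicted
#' helix count are rejected.
#'
#' @param records Topology tibble (see [read_topology_table()]).
#' @param family `"MFS"`, `"NCS1"` or `"ABC_TM"`.
#' @return The retained subset of `records`.
#' @export
filter_by_topology <- function(records, family) {
  stopifnot(is.data.frame(records))
  need_cols(records, "tm_helix_count", "topology table")
  if (!family %in% c("MFS", "NCS1", "ABC_TM")) {
    abort(sprintf("no topology rule for family `%s`.", family))
  }
  expected <- if (family == "ABC_TM") c(3, 6) else 12
  dplyr::filter(records, .data$tm_helix_count %in% expected)
}

best_hits <- function(scores) {
  # unique best hit per query; ties yield no call
  scores |>
    dplyr::group_by(.data$query_id) |>
    dplyr::filter(.data$bit_score == max(.data$bit_score)) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup()
}

#' Bidirectional best-hit (BBH) ortholog pairs
#'
#' A pair `(a, b)` across two genomes is called orthologous when `b` is the
#' unique best-scoring hit of `a` in genome B and `a` is the unique
#' best-scoring hit of `b` in genome A. Ties in either direction yield no
#' call.
#'
#' @param scores_ab Score tibble for genome-A queries against genome B
#'   (`query_id`, `subject_id`, `bit_score`).
#' @param scores_ba Score tibble for the reverse direction.
#' @return A tibble `seq_a`, `seq_b`, `score_ab`, `score_ba`, sorted by
#'   `seq_a`.
#' @export
bbh_orthologs <- function(scores_ab, scores_ba) {
  for (s in list(scores_ab, scores_ba)) {
    need_cols(s, c("query_id", "subject_id", "bit_score"), "score table")
  }
  ab <- best_hits(scores_ab)
  ba <- best_hits(scores_ba)
  out <- dplyr::inner_join(
    dplyr::select(ab, seq_a = "query_id", seq_b = "subject_id",
                  score_ab = "bit_score"),
    dplyr::select(ba, seq_b = "query_id", seq_a = "subject_id",
                  score_ba = "bit_score"),
    by = c("seq_a", "seq_b")
  )
  dplyr::arrange(out, .data$seq_a)
}

#' Classify an ABC carbohydrate-uptake operon as CUT-1 or CUT-2
#'
#' CUT-1 systems encode their transmembrane domain on two genes; their
#' nucleotide-binding protein (NBP) is frequently encoded elsewhere in the
#' genome and shared among systems, so an operon of SBP + two TM genes is
#' complete when a shared NBP exists genome-wide. CUT-2 systems encode NBP,
#' substrate-binding protein (SBP) and a single TM gene adjacently.
#'
#' @param operon_members Tibble with `seq_id` and `role` for one operon.
#' @param genome_has_shared_nbp Is an NBP encoded elsewhere in the genome
#'   (default `FALSE`)?
#' @return `"CUT-1"`, `"CUT-2"` or `"incomplete"`.
#' @export
classify_cut_subfamily <- function(operon_members,
                                   genome_has_shared_nbp = FALSE) {
  stopifnot(is.data.frame(operon_members))
  need_cols(operon_members, c("seq_id", "role"), "operon members")
  n_tm <- sum(operon_members$role == "TM")
  has_sbp <- any(operon_members$role == "SBP")
  has_nbp <- any(operon_members$role == "NBP")
  if (n_tm == 2 && has_sbp && (has_nbp || genome_has_shared_nbp)) {
    return("CUT-1")
  }
  if (n_tm == 1 && has_sbp && has_nbp) {
    return("CUT-2")
  }
  "incomplete"
}

#' Assemble the transporter inventory of surveyed genomes
#'
#' Applies the screening rules end-to-end: bit-score retention (> 100),
#' family-specific topology filters (12 TM helices for MFS and NCS-1; 3 or 6
#' for ABC TM subunits), ABC operon classification into CUT-1 / CUT-2, PTS
#' system detection (an operon of phosphotransferase components, at least 3
#' genes), and ortholog labeling from bidirectional best hits. Signal
#' peptides are recorded as annotation, not used for rejection; substrate
#' labels are carried through from the inputs.
#'
#' @param hits Hit tibble (see [read_hit_table()]).
#' @param topology Topology tibble.
#' @param operons Operon tibble.
#' @param bbh_pairs Optional tibble from [bbh_orthologs()]; pairs are
#'   labelled `O1`, `O2`, ... in `seq_a` order.
#' @param bitscore_threshold Retention threshold (default 100).
#' @return A `transporter_inventory`: list with
#'   `members` (per-sequence tibble: genome, family, system, role, topology,
#'   substrate, ortholog label), `systems` (one row per accepted transport
#'   system), `counts` (genome x family system counts) and `orthologs`.
#'   [tidy()] returns `counts`.
#' @export
assemble_inventory <- function(hits, topology, operons, bbh_pairs = NULL,
                               bitscore_threshold = 100) {
  stopifnot(is.data.frame(hits), is.data.frame(topology),
            is.data.frame(operons))
  need_cols(hits, c("query_id", "subject_id", "bit_score", "family_hint",
                    "genome"), "hit table")
  need_cols(topology, c("seq_id", "tm_helix_count", "has_signal_peptide"),
            "topology table")
  need_cols(operons, c("operon_id", "seq_id", "role", "genome"),
            "operon table")
  if (!"substrate" %in% names(hits)) hits$substrate <- NA_character_
  if (!"substrate" %in% names(operons)) operons$substrate <- NA_character_

  dangling <- setdiff(operons$seq_id, c(hits$subject_id, topology$seq_id))
  if (length(dangling) > 0) {
    abort(paste0("operon member(s) unknown to hits/topology: ",
                 paste(sort(dangling), collapse = ", ")))
  }

  retained <- filter_by_bitscore(hits, bitscore_threshold)
  annotated <- dplyr::left_join(retained, topology,
                                by = c(subject_id = "seq_id"))

  # ortholog labels, attached by sequence id
  ortho_label <- character(0)
  orthologs <- tibble::tibble(label = character(0), seq_a = character(0),
                              seq_b = character(0))
  if (!is.null(bbh_pairs) && nrow(bbh_pairs) > 0) {
    orthologs <- tibble::tibble(
      label = paste0("O", seq_len(nrow(bbh_pairs))),
      seq_a = bbh_pairs$seq_a, seq_b = bbh_pairs$seq_b
    )
    ortho_label <- setNames(
      rep(orthologs$label, 2), c(orthologs$seq_a, orthologs$seq_b)
    )
  }
  label_of <- function(ids) {
    out <- unname(ortho_label[ids])
    ifelse(is.na(out), NA_character_, out)
  }

  # single-gene families: MFS and NCS-1, one system per accepted sequence
  singles <- purrr::map_dfr(c("MFS", "NCS1"), function(fam) {
    fam_hits <- dplyr::filter(annotated, .data$family_hint == fam)
    ok <- filter_by_topology(
      dplyr::rename(fam_hits, seq_id = "subject_id"), fam
    )
    if (nrow(ok) == 0) return(NULL)
    tibble::tibble(
      genome = ok$genome, family = ifelse(fam == "NCS1", "NCS-1", fam),
      system_id = ok$seq_id, seq_id = ok$seq_id, role = "transporter",
      tm_helix_count = ok$tm_helix_count,
      has_signal_peptide = ok$has_signal_peptide,
      substrate = ok$substrate, ortholog = label_of(ok$seq_id)
    )
  })

  # operon-based families: ABC (CUT-1 / CUT-2) and PTS
  seq_family <- setNames(hits$family_hint, hits$subject_id)
  retained_ids <- unique(retained$subject_id)
  shared_nbp <- operons |>
    dplyr::filter(.data$role == "NBP", .data$seq_id %in% retained_ids) |>
    dplyr::distinct(.data$genome, .data$operon_id)

  op_rows <- list()
  sys_rows <- list()
  for (op_id in unique(operons$operon_id)) {
    members <- dplyr::filter(operons, .data$operon_id == op_id)
    genome <- members$genome[1]
    fams <- unname(seq_family[members$seq_id])
    is_pts <- any(fams == "PTS", na.rm = TRUE)
    if (is_pts) {
      classification <- if (nrow(members) >= 3) "PTS" else "incomplete"
      family <- "PTS"
    } else if (all(members$role == "NBP")) {
      next # stand-alone shared-NBP locus, not a transport system
    } else {
      family <- "ABC"
      # TM members must carry the expected ABC topology to count
      topo <- dplyr::left_join(members, topology, by = "seq_id")
      tm_ok <- topo$role == "TM" &
        topo$tm_helix_count %in% c(3, 6) &
        topo$seq_id %in% retained_ids
      eff <- members
      eff$role[members$role == "TM" & !tm_ok] <- "TM_rejected"
      other_nbp <- shared_nbp |>
        dplyr::filter(.data$genome == !!genome, .data$operon_id != op_id)
      classification <- classify_cut_subfamily(
        eff, genome_has_shared_nbp = nrow(other_nbp) > 0
      )
    }
    if (classification == "incomplete") next
    substrate <- c(members$substrate[!is.na(members$substrate)],
                   NA_character_)[1]
    sys_rows[[op_id]] <- tibble::tibble(
      genome = genome,
      family = if (family == "ABC") classification else family,
      system_id = op_id, classification = classification,
      substrate = substrate
    )
    topo_m <- dplyr::left_join(members, topology, by = "seq_id")
    op_rows[[op_id]] <- tibble::tibble(
      genome = genome,
      family = if (family == "ABC") classification else family,
      system_id = op_id, seq_id = members$seq_id, role = members$role,
      tm_helix_count = topo_m$tm_helix_count,
      has_signal_peptide = topo_m$has_signal_peptide,
      substrate = substrate, ortholog = label_of(members$seq_id)
    )
  }

  single_systems <- if (nrow(singles) > 0) {
    dplyr::distinct(singles, .data$genome, .data$family, .data$system_id,
                    .data$substrate) |>
      dplyr::mutate(classification = .data$family)
  } else {
    NULL
  }
  systems <- dplyr::bind_rows(c(list(single_systems), sys_rows))
  members_tbl <- dplyr::bind_rows(c(list(singles), op_rows))
  if (nrow(systems) == 0) {
    systems <- tibble::tibble(genome = character(0), family = character(0),
                              system_id = character(0),
                              classification = character(0),
                              substrate = character(0))
  }
  if (nrow(members_tbl) == 0) {
    members_tbl <- tibble::tibble(genome = character(0), family = character(0),
                                  system_id = character(0),
                                  seq_id = character(0), role = character(0),
                                  tm_helix_count = integer(0),
                                  has_signal_peptide = logical(0),
                                  substrate = character(0),
                                  ortholog = character(0))
  }
  counts <- systems |>
    dplyr::count(.data$genome, .data$family, name = "n_systems") |>
    dplyr::arrange(.data$genome, .data$family)

  structure(
    list(members = members_tbl, systems = systems, counts = counts,
         orthologs = orthologs),
    class = "transporter_inventory"
  )
}

#' @export
print.transporter_inventory <- function(x, ...) {
  cat(sprintf("<transporter_inventory> %d systems across %d genome(s), %d ortholog pair(s)\n",
              nrow(x$systems), dplyr::n_distinct(x$systems$genome),
              nrow(x$orthologs)))
  print(tidyr::pivot_wider(x$counts, names_from = "family",
                           values_from = "n_systems", values_fill = 0L))
  invisible(x)
}

#' @rdname assemble_inventory
#' @param x A `transporter_inventory`.
#' @param ... Unused.
#' @export
tidy.transporter_inventory <- function(x, ...) x$counts

#' Run the transporter screen from TSV inputs
#'
#' Convenience wrapper: reads the hit, topology and operon tables (and, when
#' given, the two directional score tables for best-hit orthology) and calls
#' [assemble_inventory()].
#'
#' @param hits_path,topology_path,operons_path Input TSV paths.
#' @param scores_ab_path,scores_ba_path Optional directional score TSVs.
#' @param bitscore_threshold Retention threshold (default 100).
#' @return A `transporter_inventory`.
#' @export
screen_transporters <- function(hits_path, topology_path, operons_path,
                                scores_ab_path = NULL, scores_ba_path = NULL,
                                bitscore_threshold = 100) {
  hits <- read_hit_table(hits_path)
  topology <- read_topology_table(topology_path)
  operons <- read_operon_table(operons_path)
  pairs <- NULL
  if (!is.null(scores_ab_path) && !is.null(scores_ba_path)) {
    pairs <- bbh_orthologs(read_score_table(scores_ab_path),
                           read_score_table(scores_ba_path))
  }
  assemble_inventory(hits, topology, operons, bbh_pairs = pairs,
                     bitscore_threshold = bitscore_threshold)
}

#' Write a transporter inventory to disk
#'
#' @param inventory A `transporter_inventory`.
#' @param json_path Output JSON path (counts, systems, orthologs).
#' @param tsv_dir Optional directory for per-family member TSVs.
#' @return `json_path`, invisibly.
#' @export
write_inventory <- function(inventory, json_path, tsv_dir = NULL) {
  stopifnot(inherits(inventory, "transporter_inventory"))
  jsonlite::write_json(
    list(counts = inventory$counts, systems = inventory$systems,
         orthologs = inventory$orthologs),
    json_path, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE
  )
  if (!is.null(tsv_dir)) {
    dir.create(tsv_dir, recursive = TRUE, showWarnings = FALSE)
    for (fam in unique(inventory$members$family)) {
      readr::write_tsv(
        dplyr::filter(inventory$members, .data$family == fam),
        file.path(tsv_dir, paste0(gsub("[^A-Za-z0-9]", "_", fam), ".tsv"))
      )
    }
  }
  invisible(json_path)
}
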