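# SDF input/output.  Reading goes through ChemmineR's SDF parser; writing
# emits fixed-format V2000 records, one per conformer, with CID/LID data
# fields.

#' Read a multi-conformer SD file
#'
#' Records are grouped into compounds by the CID data field and ordered by
#' LID.  Records without either field fall back to sequential numbering
#' (each record its own compound, LID 0).  Hydrogens are kept in the
#' structure but flagged.  Records without 3-D coordinates (all-zero z
#' column) are skipped with a warning.
#'
#' @param path Path to an SD file (V2000).
#' @param cid_field,lid_field Names of the SDF data fields carrying the
#'   compound and local conformer identifiers.
#' @param energy_field Optional data field with the relative conformer
#'   energy (kcal/mol).
#' @return A list of `compound_record` objects.
#' @export
read_sdf <- function(path, cid_field = "PUBCHEM_COMPOUND_CID",
                     lid_field = "PUBCHEM_CONFORMER_LID",
                     energy_field = "PUBCHEM_CONFORMER_ENERGY") {
  sdfset <- ChemmineR::read.SDFset(path)
  confs <- list()
  fallback_cid <- 0
  for (k in seq_along(ChemmineR::sdfid(sdfset))) {
    sdf <- sdfset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    if (nrow(ab) == 0) {
      warning("record ", k, ": empty atom block, skipped")
      next
    }
    coords <- ab[, 1:3, drop = FALSE]
    if (nrow(coords) > 1 && all(abs(coords) < 1e-8)) {
      warning("record ", k, ": no coordinates, skipped")
      next
    }
    elements <- sub("_.*$", "", rownames(ab))
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (is.matrix(bb) && nrow(bb) > 0) {
      unname(cbind(bb[, 1], bb[, 2], bb[, 3]))
    } else NULL
    db <- ChemmineR::datablock(sdf)
    getf <- function(f) {
      v <- suppressWarnings(as.numeric(db[f]))
      if (length(v) == 1 && !is.na(v)) v else NA_real_
    }
    cid <- getf(cid_field); lid <- getf(lid_field)
    if (is.na(cid)) {
      fallback_cid <- fallback_cid + 1
      cid <- fallback_cid
      lid <- 0
    } else if (is.na(lid)) lid <- 0
    confs[[length(confs) + 1L]] <- conformer(
      elements, coords, bonds = bonds, cid = cid, lid = lid,
      energy = getf(energy_field))
  }
  cids <- vapply(confs, function(x) x$cid, numeric(1))
  lapply(sort(unique(cids)), function(cid) {
    compound_record(cid, confs[cids == cid])
  })
}

.sdf_record <- function(conf, cid_field, lid_field, energy_field) {
  n <- length(conf$elements)
  nb <- if (is.null(conf$bonds)) 0L else nrow(conf$bonds)
  lines <- c(
    sprintf("CID%s LID%s", format(conf$cid, scientific = FALSE), conf$lid),
    "  p3dnbr          3D", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            conf$coords[, 1], conf$coords[, 2], conf$coords[, 3],
            conf$elements))
  if (nb > 0) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", conf$bonds[, 1],
                              conf$bonds[, 2], conf$bonds[, 3]))
  }
  lines <- c(lines, "M  END",
             sprintf(">  <%s>", cid_field),
             format(conf$cid, scientific = FALSE), "",
             sprintf(">  <%s>", lid_field),
             format(conf$lid, scientific = FALSE), "")
  if (!is.na(conf$energy)) {
    lines <- c(lines, sprintf(">  <%s>", energy_field),
               format(conf$energy), "")
  }
  c(lines, "$$$$")
}

#' Write compound records to an SD file
#'
#' One V2000 record per conformer, coordinates at 1e-4 angstrom precision,
#' identity carried in CID/LID data fields so [read_sdf()] round-trips.
#'
#' @param records List of `compound_record` objects (or a single record, or
#'   a list of `conformer` objects).
#' @param path Output path.
#' @inheritParams read_sdf
#' @return Invisibly, the path.
#' @export
write_sdf <- function(records, path, cid_field = "PUBCHEM_COMPOUND_CID",
                      lid_field = "PUBCHEM_CONFORMER_LID",
                      energy_field = "PUBCHEM_CONFORMER_ENERGY") {
  if (inherits(records, "compound_record")) records <- list(records)
  confs <- list()
  for (r in records) {
    if (inherits(r, "conformer")) confs <- c(confs, list(r))
    else confs <- c(confs, r$conformers)
  }
  lines <- unlist(lapply(confs, .sdf_record, cid_field = cid_field,
                         lid_field = lid_field, energy_field = energy_field))
  writeLines(if (is.null(lines)) character(0) else lines, path)
  invisible(path)
}
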