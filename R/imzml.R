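#' @title imzML input and output
#' @description
#' Minimal but conformant reader/writer for the imzML standard (mzML-style
#' XML index plus an external `.ibd` binary file holding the m/z and
#' intensity arrays). Both the processed dialect (per-spectrum m/z axes)
#' and the continuous dialect (one shared m/z axis) are supported. imzML's
#' 1-based pixel coordinates are converted to the package's 0-based
#' `(row, col)` grid at this boundary: file `x` maps to `col + 1`, `y` to
#' `row + 1`.
#' @name imzml-io
NULL

msi_error <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

ibd_path_for <- function(path) {
  sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
}

format_uuid <- function(raw16) {
  h <- paste(sprintf("%02x", as.integer(raw16)), collapse = "")
  paste0("{", substr(h, 1, 8), "-", substr(h, 9, 12), "-", substr(h, 13, 16),
         "-", substr(h, 17, 20), "-", substr(h, 21, 32), "}")
}

#' Write an MSI dataset to imzML + ibd
#'
#' @param dataset An [msi_dataset()].
#' @param path Output path ending in `.imzML`; the binary companion is
#'   written next to it with extension `.ibd`.
#' @param mode `"processed"` (default; per-spectrum m/z axes) or
#'   `"continuous"` (all spectra must share an identical m/z axis, which is
#'   stored once).
#' @return `path`, invisibly.
#' @export
write_imzml <- function(dataset, path, mode = c("processed", "continuous")) {
  stopifnot(inherits(dataset, "msi_dataset"))
  mode <- match.arg(mode)
  ibd <- ibd_path_for(path)
  n <- length(dataset$spectra)
  if (mode == "continuous" && n > 1) {
    mz0 <- dataset$spectra[[1]]$mz
    same <- all(vapply(dataset$spectra, function(s)
      length(s$mz) == length(mz0) && all(s$mz == mz0), logical(1)))
    if (!same) stop("continuous mode requires identical m/z axes")
  }
  uuid <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  con <- file(ibd, "wb")
  writeBin(uuid, con)
  offset <- 16
  mz_off <- mz_len <- int_off <- int_len <- numeric(n)
  shared_mz_off <- NULL
  for (i in seq_len(n)) {
    s <- dataset$spectra[[i]]
    nl <- length(s$mz)
    if (mode == "continuous") {
      if (is.null(shared_mz_off)) {
        shared_mz_off <- offset
        writeBin(as.numeric(s$mz), con, size = 8, endian = "little")
        offset <- offset + 8 * nl
      }
      mz_off[i] <- shared_mz_off
    } else {
      mz_off[i] <- offset
      writeBin(as.numeric(s$mz), con, size = 8, endian = "little")
      offset <- offset + 8 * nl
    }
    mz_len[i] <- nl
    int_off[i] <- offset
    writeBin(as.numeric(s$intensity), con, size = 8, endian = "little")
    offset <- offset + 8 * nl
    int_len[i] <- nl
  }
  close(con)
  md5 <- unname(tools::md5sum(ibd))

  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", as.character(x)))
  head <- c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '  <cvList count="3">',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
    '    <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
    '    <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
    '  </cvList>',
    '  <fileDescription>',
    '    <fileContent>',
    '      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:%s" name="%s" value=""/>',
            if (mode == "processed") "1000031" else "1000030", mode),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="%s"/>',
            format_uuid(uuid)),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000090" name="ibd MD5" value="%s"/>',
            toupper(md5)),
    sprintf('      <userParam name="lipidmsi:section_id" value="%s"/>', esc(dataset$section_id)),
    sprintf('      <userParam name="lipidmsi:disease_class" value="%s"/>', esc(dataset$disease_class)),
    sprintf('      <userParam name="lipidmsi:polarity" value="%s"/>', dataset$polarity),
    '    </fileContent>',
    '  </fileDescription>',
    '  <referenceableParamGroupList count="2">',
    '    <referenceableParamGroup id="mzArray">',
    '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '    </referenceableParamGroup>',
    '    <referenceableParamGroup id="intensityArray">',
    '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '    </referenceableParamGroup>',
    '  </referenceableParamGroupList>',
    '  <softwareList count="1">',
    '    <software id="lipidmsi" version="0.1.0"/>',
    '  </softwareList>',
    '  <scanSettingsList count="1">',
    '    <scanSettings id="scanSettings1">',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>', dataset$grid_shape[2]),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>', dataset$grid_shape[1]),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size x" value="%g"/>', dataset$pixel_size_um),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%g"/>', dataset$pixel_size_um),
    '    </scanSettings>',
    '  </scanSettingsList>',
    '  <instrumentConfigurationList count="1">',
    '    <instrumentConfiguration id="IC1"/>',
    '  </instrumentConfigurationList>',
    '  <dataProcessingList count="1">',
    '    <dataProcessing id="export">',
    '      <processingMethod order="1" softwareRef="lipidmsi">',
    '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '      </processingMethod>',
    '    </dataProcessing>',
    '  </dataProcessingList>',
    sprintf('  <run id="run1" defaultInstrumentConfigurationRef="IC1">'),
    sprintf('    <spectrumList count="%d" defaultDataProcessingRef="export">', n))

  spec_xml <- character(n)
  for (i in seq_len(n)) {
    x <- dataset$coords[i, 2] + 1L
    y <- dataset$coords[i, 1] + 1L
    nl <- mz_len[i]
    spec_xml[i] <- paste0(
      sprintf('      <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">\n', i - 1L, i, nl),
      '        <scanList count="1">\n',
      '          <scan>\n',
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n', x),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n', y),
      '          </scan>\n',
      '        </scanList>\n',
      '        <binaryDataArrayList count="2">\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="mzArray"/>\n',
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', nl),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n', 8L * nl),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n', mz_off[i]),
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="intensityArray"/>\n',
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', nl),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n', 8L * nl),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n', int_off[i]),
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '        </binaryDataArrayList>\n',
      '      </spectrum>')
  }
  tail <- c('    </spectrumList>', '  </run>', '</mzML>')
  writeLines(c(head, spec_xml, tail), path)
  invisible(path)
}

#' Read an imzML + ibd file pair into an MSI dataset
#'
#' Both the processed and the continuous dialect are read into the same
#' `msi_dataset` container. The ibd UUID and (when present) its MD5
#' checksum are verified. Errors are signalled with distinct condition
#' classes: `lipidmsi_missing_ibd`, `lipidmsi_checksum_mismatch`,
#' `lipidmsi_malformed_imzml`.
#'
#' @param path Path to the `.imzML` file.
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path) {
  if (!file.exists(path))
    msi_error("lipidmsi_malformed_imzml", paste("no such file:", path))
  ibd <- ibd_path_for(path)
  if (!file.exists(ibd))
    msi_error("lipidmsi_missing_ibd", paste("missing ibd companion:", ibd))
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    msi_error("lipidmsi_malformed_imzml", paste("cannot parse imzML XML:", conditionMessage(e))))
  xml2::xml_ns_strip(doc)

  cv_value <- function(node, accession) {
    n <- xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", accession))
    if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_attr(n, "value")
  }
  fc <- xml2::xml_find_first(doc, ".//fileDescription/fileContent")
  if (inherits(fc, "xml_missing"))
    msi_error("lipidmsi_malformed_imzml", "no fileContent element")
  uuid_str <- cv_value(fc, "IMS:1000080")
  md5_str <- cv_value(fc, "IMS:1000090")

  # ibd header checks
  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)
  uuid_raw <- readBin(con, "raw", 16)
  if (!is.na(uuid_str)) {
    want <- tolower(gsub("[{}-]", "", uuid_str))
    got <- paste(sprintf("%02x", as.integer(uuid_raw)), collapse = "")
    if (nzchar(want) && want != got)
      msi_error("lipidmsi_checksum_mismatch",
                "ibd UUID does not match the imzML header")
  }
  if (!is.na(md5_str) && nzchar(md5_str)) {
    got <- toupper(unname(tools::md5sum(ibd)))
    if (toupper(md5_str) != got)
      msi_error("lipidmsi_checksum_mismatch", "ibd MD5 checksum mismatch")
  }

  # array precision per referenceable param group
  grp_nodes <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  grp_size <- list()
  for (g in grp_nodes) {
    id <- xml2::xml_attr(g, "id")
    sz <- if (!is.na(cv_value(g, "MS:1000521"))) 4L else 8L
    grp_size[[id]] <- sz
  }
  user_value <- function(name) {
    n <- xml2::xml_find_first(doc, sprintf(".//userParam[@name='%s']", name))
    if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_attr(n, "value")
  }

  specs <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (!length(specs))
    msi_error("lipidmsi_malformed_imzml", "no spectra in imzML")
  n <- length(specs)
  spectra <- vector("list", n)
  coords <- matrix(0L, n, 2, dimnames = list(NULL, c("row", "col")))
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    x <- as.integer(cv_value(sp, "IMS:1000050"))
    y <- as.integer(cv_value(sp, "IMS:1000051"))
    if (is.na(x) || is.na(y))
      msi_error("lipidmsi_malformed_imzml", "spectrum without pixel position")
    coords[i, ] <- c(y - 1L, x - 1L)
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    vals <- list(mz = NULL, intensity = NULL)
    for (a in arrays) {
      ref <- xml2::xml_attr(xml2::xml_find_first(a, "referenceableParamGroupRef"), "ref")
      is_mz <- if (!is.na(ref)) grepl("mz", ref, ignore.case = TRUE)
               else !is.na(cv_value(a, "MS:1000514"))
      size <- if (!is.na(ref) && !is.null(grp_size[[ref]])) grp_size[[ref]]
              else if (!is.na(cv_value(a, "MS:1000521"))) 4L else 8L
      off <- as.numeric(cv_value(a, "IMS:1000102"))
      len <- as.integer(cv_value(a, "IMS:1000103"))
      if (is.na(off) || is.na(len))
        msi_error("lipidmsi_malformed_imzml", "binary array without offset/length")
      seek(con, where = off, origin = "start")
      v <- readBin(con, "double", n = len, size = size, endian = "little")
      if (is_mz) vals$mz <- v else vals$intensity <- v
    }
    if (is.null(vals$mz) || is.null(vals$intensity))
      msi_error("lipidmsi_malformed_imzml", "spectrum missing m/z or intensity array")
    spectra[[i]] <- vals
  }
  gx <- as.integer(cv_value(doc, "IMS:1000042"))
  gy <- as.integer(cv_value(doc, "IMS:1000043"))
  grid_shape <- c(if (is.na(gy)) max(coords[, 1]) + 1L else gy,
                  if (is.na(gx)) max(coords[, 2]) + 1L else gx)
  px <- as.numeric(cv_value(doc, "IMS:1000046"))
  polarity <- user_value("lipidmsi:polarity")
  if (is.na(polarity)) polarity <- "positive"
  section_id <- user_value("lipidmsi:section_id")
  if (is.na(section_id)) section_id <- basename(path)
  dclass <- user_value("lipidmsi:disease_class")
  if (is.na(dclass)) dclass <- "unknown"
  msi_dataset(spectra = spectra, coords = coords, grid_shape = grid_shape,
              pixel_size_um = if (is.na(px)) 45 else px, polarity = polarity,
              section_id = section_id, disease_class = dclass)
}
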