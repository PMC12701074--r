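# Shared fixtures built in code.

fig2_pair <- function(linker) {
  crosslink_pair("Ac-SAKAYEHR:K3", "Ac-LADVCAHER:C5", linker)
}

# spectrum containing exactly the theoretical signature fragments of a pair
signature_spectrum <- function(pair, z = 4, extra_mz = numeric(),
                               drop = character(), scan = 1L) {
  sig <- signature_fragment_mzs(pair)
  sig <- sig[!(sig$fragment %in% drop), ]
  mz <- c(sig$mz, extra_mz)
  spectrum_row(scan, 2L, mz = mz, intensity = rep(1e5, length(mz)),
               precursor_mz = precursor_mz(pair, z), precursor_charge = z)
}

# straight-line homodimer where residue identities follow KACG repeats
toy_dimer <- function(n_res = 40, offset = 12, id = "TOY1") {
  simulate_toy_structure(n_res = n_res, homodimer_offset = offset,
                         structure_id = id)
}

toy_mapping <- function(protein = "P1", id = "TOY1", chains = c("A", "B")) {
  tibble::tibble(protein = protein, structure_id = id, chain = chains,
                 offset = 0L)
}

# minimal linkage table with the columns downstream functions use
mk_linkages <- function(protein_a, res_a, protein_b, res_b,
                        linkers = NULL, replicates = NULL,
                        ambiguous = FALSE) {
  n <- length(protein_a)
  if (is.null(linkers)) linkers <- rep(list("SIA"), n)
  if (is.null(replicates)) replicates <- rep(list("rep1"), n)
  tibble::tibble(
    protein_a = protein_a, res_a = as.integer(res_a),
    protein_b = protein_b, res_b = as.integer(res_b),
    intra = protein_a == protein_b,
    ambiguous = ambiguous,
    linkers = linkers,
    support = purrr::map2(linkers, replicates, function(l, r) {
      tidyr::expand_grid(linker = unlist(l), replicate = unlist(r)) |>
        dplyr::mutate(n_csms = 1L)
    })
  )
}

# Minimal mzML writer for fixtures (64-bit little-endian, no compression).
write_minimal_mzml <- function(run, path) {
  b64 <- function(x) {
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                  endian = "little"))
  }
  arr <- function(v, acc, nm) {
    sprintf(paste0(
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="%s" name="%s" value=""/>',
      '<binary>%s</binary></binaryDataArray>'),
      nchar(b64(v)), acc, nm, b64(v))
  }
  spec_xml <- function(i) {
    pk <- run$peaks[[i]]
    prec_xml <- ""
    if (run$ms_level[i] > 1) {
      ref <- if (!is.na(run$parent_scan[i])) {
        sprintf(' spectrumRef="scan=%d"', run$parent_scan[i])
      } else ""
      prec_xml <- sprintf(paste0(
        '<precursorList count="1"><precursor%s>',
        '<selectedIonList count="1"><selectedIon>',
        '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f"/>',
        '<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>',
        '</selectedIon></selectedIonList><activation>',
        '<cvParam cvRef="MS" accession="MS:1000133" name="collision-induced dissociation" value=""/>',
        '</activation></precursor></precursorList>'),
        ref, run$precursor_mz[i], run$precursor_charge[i])
    }
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
      '%s<binaryDataArrayList count="2">%s%s</binaryDataArrayList></spectrum>'),
      i - 1, run$scan[i], nrow(pk), run$ms_level[i], prec_xml,
      arr(pk$mz, "MS:1000514", "m/z array"),
      arr(pk$intensity, "MS:1000515", "intensity array"))
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/></fileContent></fileDescription>',
    '<softwareList count="1"><software id="sw" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="ic"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>',
    '<run id="r1" defaultInstrumentConfigurationRef="ic">',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp">', nrow(run)),
    paste(vapply(seq_len(nrow(run)), spec_xml, character(1)), collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(doc, path)
  invisible(path)
}
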