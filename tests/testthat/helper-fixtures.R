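# Shared fixtures built in code at test time.

# a minimal experiment with hand-placed peaks at one (step, polarity)
makeTinySpectrum <- function(step, polarity, mz, intensity) {
  msmsSpectrum(step, polarity, data.frame(mz = mz, intensity = intensity))
}

makeTinyExperiment <- function(spectra, spikes = NULL, sample = "tiny") {
  msmsExperiment(sample, spectra, spikeSheet = spikes)
}

# write a minimal single-MS2-scan mzML file (uncompressed 64-bit arrays)
writeMiniMzml <- function(path, mz, intensity, precursorMz,
                          polarity = "positive") {
  b64 <- function(x)
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                  endian = "little"))
  mzb <- b64(mz); inb <- b64(intensity)
  polAcc <- if (polarity == "positive") "MS:1000130" else "MS:1000129"
  polName <- paste(polarity, "scan")
  lines <- c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/></fileContent></fileDescription>',
    '<softwareList count="1"><software id="sw" version="1.0"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    '<spectrumList count="1" defaultDataProcessingRef="dp">',
    sprintf('<spectrum index="0" id="scan=1" defaultArrayLength="%d">',
            length(mz)),
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>',
    sprintf('<cvParam cvRef="MS" accession="%s" name="%s" value=""/>',
            polAcc, polName),
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    '<precursorList count="1"><precursor><isolationWindow>',
    sprintf('<cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%g" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
            precursorMz),
    '</isolationWindow><selectedIonList count="1"><selectedIon>',
    sprintf('<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%g" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
            precursorMz),
    '</selectedIon></selectedIonList><activation><cvParam cvRef="MS" accession="MS:1000422" name="beam-type collision-induced dissociation" value=""/></activation></precursor></precursorList>',
    '<binaryDataArrayList count="2">',
    sprintf('<binaryDataArray encodedLength="%d">', nchar(mzb)),
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    sprintf('<binary>%s</binary>', mzb),
    '</binaryDataArray>',
    sprintf('<binaryDataArray encodedLength="%d">', nchar(inb)),
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
    sprintf('<binary>%s</binary>', inb),
    '</binaryDataArray>',
    '</binaryDataArrayList></spectrum></spectrumList></run></mzML>')
  writeLines(lines, path)
  invisible(path)
}

# identification recall against the ground truth of a fixture
identificationRecall <- function(result, fixtureName) {
  truth <- groundTruthSpecies(makeFixture(fixtureName))
  ids <- result$identifications
  ids <- ids[!ids$internalStandard, , drop = FALSE]
  mean(truth$species %in% ids$species)
}
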