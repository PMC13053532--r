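# Writes small DICOM fixtures at test time with pydicom (an independent
# implementation of the format), so the in-package reader is checked against
# a third-party writer rather than against itself.

write_test_dicom <- function(path, values, bits = 16L,
                             photometric = "MONOCHROME2",
                             implicit = FALSE) {
  csv <- tempfile(fileext = ".csv")
  utils::write.table(values, csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "import numpy as np",
    "import pydicom",
    "from pydicom.dataset import Dataset, FileDataset, FileMetaDataset",
    "from pydicom.uid import ExplicitVRLittleEndian, ImplicitVRLittleEndian, generate_uid",
    "out, csv, bits, photometric, implicit = sys.argv[1:6]",
    "bits = int(bits)",
    "arr = np.loadtxt(csv, delimiter=',', ndmin=2)",
    "dtype = np.uint8 if bits <= 8 else np.uint16",
    "arr = arr.astype(dtype)",
    "meta = FileMetaDataset()",
    "meta.MediaStorageSOPClassUID = pydicom.uid.SecondaryCaptureImageStorage",
    "meta.MediaStorageSOPInstanceUID = generate_uid()",
    "meta.TransferSyntaxUID = ImplicitVRLittleEndian if implicit == '1' else ExplicitVRLittleEndian",
    "ds = FileDataset(out, {}, file_meta=meta, preamble=b'\\x00' * 128)",
    "ds.SOPClassUID = meta.MediaStorageSOPClassUID",
    "ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID",
    "ds.Modality = 'OT'",
    "ds.Rows, ds.Columns = arr.shape",
    "ds.SamplesPerPixel = 1",
    "ds.PhotometricInterpretation = photometric",
    "ds.BitsAllocated = 8 if bits <= 8 else 16",
    "ds.BitsStored = bits",
    "ds.HighBit = bits - 1",
    "ds.PixelRepresentation = 0",
    "ds.PixelData = arr.tobytes()",
    "ds.save_as(out, enforce_file_format=True)"
  ), script)
  status <- system2("python", c(script, path, csv, bits, photometric,
                                if (implicit) "1" else "0"),
                    stdout = FALSE, stderr = FALSE)
  # arg order: script out csv bits photometric implicit
  status == 0 && file.exists(path)
}
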