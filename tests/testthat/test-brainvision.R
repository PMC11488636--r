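test_that("write-read round trip preserves samples and markers", {
  set.seed(201)
  rec <- eeg_recording(matrix(rnorm(3 * 2500), 3), rate = 250,
                       channel_labels = c("Fz", "Cz", "Pz"),
                       markers = data.frame(
                         time = c(0.4, 2, 6.5),
                         label = c("Watch", "Regulate", "Watch")))
  base <- file.path(tempdir(), "bv_roundtrip")
  write_brainvision(rec, base)
  r2 <- read_brainvision(base)
  expect_lt(max(abs(r2$data - rec$data)), 1e-6)  # float32 precision
  expect_equal(r2$markers$time, rec$markers$time)
  expect_equal(r2$markers$label, rec$markers$label)
  expect_equal(r2$rate, 250)
  expect_equal(r2$channel_labels, c("Fz", "Cz", "Pz"))
})

test_that("the header records a 4000-microsecond sampling interval at 250 Hz", {
  rec <- eeg_recording(matrix(0, 1, 250), rate = 250,
                       channel_labels = "Pz")
  base <- file.path(tempdir(), "bv_hdr")
  write_brainvision(rec, base)
  hdr <- readLines(paste0(base, ".vhdr"))
  expect_true("SamplingInterval=4000" %in% hdr)
  expect_true("BinaryFormat=IEEE_FLOAT_32" %in% hdr)
  expect_true("DataOrientation=MULTIPLEXED" %in% hdr)
})

test_that("INT_16 data are scaled by the channel resolution", {
  base <- file.path(tempdir(), "bv_int16")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", basename(base), ".eeg"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    "NumberOfChannels=1",
    "SamplingInterval=4000",
    "[Binary Infos]",
    "BinaryFormat=INT_16",
    "[Channel Infos]",
    "Ch1=Pz,,0.1,µV"), paste0(base, ".vhdr"))
  con <- file(paste0(base, ".eeg"), "wb")
  writeBin(c(-100L, 0L, 250L, 1000L), con, size = 2, endian = "little")
  close(con)
  rec <- read_brainvision(base)
  expect_equal(as.numeric(rec$data[1, ]), c(-10, 0, 25, 100))
})

test_that("truncated data files report expected vs found frame counts", {
  rec <- eeg_recording(matrix(rnorm(2 * 100), 2), rate = 250,
                       channel_labels = c("Cz", "Pz"))
  base <- file.path(tempdir(), "bv_trunc")
  write_brainvision(rec, base)
  sz <- file.info(paste0(base, ".eeg"))$size
  con <- file(paste0(base, ".eeg"), "r+b")
  truncate_at <- sz - 5  # no longer a whole number of frames
  raw_all <- readBin(con, "raw", n = sz)
  close(con)
  writeBin(raw_all[1:truncate_at], paste0(base, ".eeg"))
  expect_error(read_brainvision(base), "truncated")
})

test_that("unsupported encodings are rejected by name", {
  base <- file.path(tempdir(), "bv_bad")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "DataFormat=BINARY",
    "DataOrientation=VECTORIZED",
    "NumberOfChannels=1",
    "SamplingInterval=4000",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    "Ch1=Pz,,1,µV"), paste0(base, ".vhdr"))
  expect_error(read_brainvision(base), "VECTORIZED")
})

test_that("an independent reader agrees on samples, rate and markers", {
  # cross-check the dialect against MNE-Python's BrainVision reader
  set.seed(202)
  rec <- eeg_recording(matrix(rnorm(2 * 1000), 2), rate = 250,
                       channel_labels = c("Cz", "Pz"),
                       markers = data.frame(time = c(0.4, 2),
                                            label = c("Watch", "Regulate")))
  base <- file.path(tempdir(), "bv_mne")
  write_brainvision(rec, base)
  py <- sprintf(paste0(
    "import mne, json\n",
    "raw = mne.io.read_raw_brainvision('%s.vhdr', preload=True,",
    " verbose='ERROR')\n",
    "print(json.dumps({'sfreq': raw.info['sfreq'],",
    " 'ch': raw.ch_names,",
    " 'pz': (raw.get_data()[1, :5] * 1e6).tolist(),",
    " 'onsets': list(raw.annotations.onset),",
    " 'desc': list(raw.annotations.description)}))\n"), base)
  out <- system2("python", "-", input = py, stdout = TRUE, stderr = FALSE)
  parsed <- jsonlite::fromJSON(out[length(out)])
  expect_equal(parsed$sfreq, 250)
  expect_equal(parsed$ch, c("Cz", "Pz"))
  expect_equal(parsed$pz, rec$data[2, 1:5], tolerance = 1e-6)
  keep <- parsed$desc != "New Segment"
  expect_equal(parsed$onsets[keep], c(0.4, 2))
  expect_equal(parsed$desc[keep], c("Stimulus/Watch", "Stimulus/Regulate"))
})
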