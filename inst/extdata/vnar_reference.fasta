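>vnar_reference_synthetic synthetic region-annotated vNAR reference frame
ARVDQTPQTITKETGESCVLTNSATGYATYWYRKNPGSSNQERISIGGRYVETVNSGSKSFSLRIKDCARSGAYGSSYDVWGQGTAVTVN
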