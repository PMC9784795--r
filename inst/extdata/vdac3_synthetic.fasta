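>VDAC3_SYNTHETIC Mus musculus VDAC3-like synthetic reference (283 aa; mature 2-283); invented filler between published peptide coordinates
MCNTPTYCDLGKAAKDVFNKGYGFGMVKIDLKTKSCSGVEFSTSGHAYTDTGKVTGTLET
KYKVCNYGLTFTQKWNTDNTLGTEISWENKLAEGLKLTLDTIFVPNTGKSGKLKASYKRR
DCFSLGSNVDIDFSGPTIYGWAVLAFEGWLAGYQMSFDTAKSKLSQNNFALGYKTGDFQL
HTNVNDGTEFGGSIYQKVNDKIETSINLAWTAGSNNTRFGLAAKYKLDCRTSLVDKVNNA
SLIGLGYTQTLRPGVKLTLSALIDGKNFNAGGHKLGLGLEFEA
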