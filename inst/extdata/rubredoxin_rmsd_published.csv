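temperature_K,technique,rmsd_A
4,NRVS,0.06
4,MOSSBAUER,0.06
40,NRVS,0.075
40,MOSSBAUER,0.068
40,NFS,0.067
40,MD_EXTERNAL,0.068
110,DIFFRACTION,0.23
110,NRVS,0.10
110,MOSSBAUER,0.10
110,MD_EXTERNAL,0.11
123,DIFFRACTION,0.28
123,NRVS,0.11
123,MOSSBAUER,0.10
123,MD_EXTERNAL,0.11
160,DIFFRACTION,0.30
160,NRVS,0.12
160,MOSSBAUER,0.12
160,NFS,0.12
160,MD_EXTERNAL,0.13
200,DIFFRACTION,0.27
200,NRVS,0.13
200,MOSSBAUER,0.13
200,NFS,0.14
200,MD_EXTERNAL,0.15
235,DIFFRACTION,0.34
235,NRVS,0.14
235,MOSSBAUER,0.18
235,NFS,0.16
235,MD_EXTERNAL,0.17
250,NRVS,0.15
250,MD_EXTERNAL,0.18
295,DIFFRACTION,0.33
295,NRVS,0.16
295,MD_EXTERNAL,0.20
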