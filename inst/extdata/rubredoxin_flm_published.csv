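temperature_K,protein,technique,f_LM
4.2,Pf,MOSSBAUER,0.82
4.2,Pg,MOSSBAUER,0.82
18,Pf,NFS,0.82
18,Pg,NFS,0.84
40,Pf,MOSSBAUER,0.78
40,Pf,NFS,0.77
40,Pg,MOSSBAUER,0.69
40,Pg,NFS,0.78
90,Pf,MOSSBAUER,0.63
90,Pf,NFS,0.65
90,Pg,MOSSBAUER,0.59
90,Pg,NFS,0.66
100,Pf,MOSSBAUER,0.62
100,Pf,NFS,0.63
100,Pg,MOSSBAUER,0.58
100,Pg,NFS,0.63
120,Pf,MOSSBAUER,0.60
120,Pf,NFS,0.58
120,Pg,MOSSBAUER,0.55
120,Pg,NFS,0.58
150,Pf,MOSSBAUER,0.59
150,Pf,NFS,0.51
150,Pg,MOSSBAUER,0.40
150,Pg,NFS,0.51
180,Pf,MOSSBAUER,0.53
180,Pf,NFS,0.43
180,Pg,MOSSBAUER,0.38
180,Pg,NFS,0.43
200,Pf,MOSSBAUER,0.44
200,Pf,NFS,0.39
200,Pg,MOSSBAUER,0.50
200,Pg,NFS,0.38
220,Pf,MOSSBAUER,0.42
220,Pf,NFS,0.34
220,Pg,MOSSBAUER,0.32
220,Pg,NFS,0.33
235,Pf,MOSSBAUER,0.17
235,Pf,NFS,0.25
235,Pg,MOSSBAUER,0.34
235,Pg,NFS,0.25
250,Pf,MOSSBAUER,0.04
250,Pg,MOSSBAUER,0.04
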