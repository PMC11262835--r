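!gaf-version: 2.2
! Synthetic 5-protein annotation set on the diamond-DAG toy ontology
! (diamond.obo): d -> {b, c}, b -> a, c -> a, a -> MF root.
! Leaf annotations: P1 d; P2 b; P3 c; P4 b; P5 b and c.
! After ancestor closure the per-term protein counts are
!   C(a)=5, C(b)=4, C(c)=3, C(d)=1
! and the joint direct-parent counts are
!   C(par a)=5 (root), C(par b)=C(par c)=5 (a), C(par d)=2 ({b,c}: P1, P5).
toyDB	P1	P1	enables	GO:7000004	REF:0000001	IDA		F			protein	taxon:0	20240101	toyDB
toyDB	P2	P2	enables	GO:7000002	REF:0000001	IDA		F			protein	taxon:0	20240101	toyDB
toyDB	P3	P3	enables	GO:7000003	REF:0000001	IMP		F			protein	taxon:0	20240101	toyDB
toyDB	P4	P4	enables	GO:7000002	REF:0000001	TAS		F			protein	taxon:0	20240101	toyDB
toyDB	P5	P5	enables	GO:7000002	REF:0000001	EXP		F			protein	taxon:0	20240101	toyDB
toyDB	P5	P5	enables	GO:7000003	REF:0000001	IDA		F			protein	taxon:0	20240101	toyDB
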