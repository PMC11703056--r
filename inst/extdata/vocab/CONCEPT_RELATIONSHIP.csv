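concept_id_1	concept_id_2	relationship_id	valid_start_date	valid_end_date	invalid_reason
45000001	201826	Maps to	1970-01-01	2099-12-31
45000002	316866	Maps to	1970-01-01	2099-12-31
45000003	255573	Maps to	1970-01-01	2099-12-31
45000004	80809	Maps to	1970-01-01	2099-12-31
45000005	37311061	Maps to	1970-01-01	2099-12-31
45000006	440383	Maps to	1970-01-01	2099-12-31
45000007	4271013	Maps to	1970-01-01	2099-12-31
45000008	46271022	Maps to	1970-01-01	2099-12-31
45000009	193782	Maps to	1970-01-01	2099-12-31
45000009	4032243	Maps to	1970-01-01	2099-12-31
45000010	4082452	Maps to	1970-01-01	2099-12-31
45000011	4299535	Maps to	1970-01-01	2099-12-31
46000001	4301351	Maps to	1970-01-01	2099-12-31
46000002	4144921	Maps to	1970-01-01	2099-12-31
46000003	19078097	Maps to	1970-01-01	2099-12-31
46000004	4154954	Maps to	1970-01-01	2099-12-31
46000005	4219859	Maps to	1970-01-01	2099-12-31
201826	201826	Maps to	1970-01-01	2099-12-31
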