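"id","text","exam_date","age","exam_code"
"SYN00001","Clinical history: Hypothyroidism on levothyroxine.

Findings: Ultrasound assessment of the thyroid gland. Appearances are in keeping with a multinodular goitre. Features are consistent with thyroiditis. A thyroglossal cyst is demonstrated in the midline. The trachea is central and the carotid arteries are patent. The appearances are stable. The visualised soft tissues of the neck are unremarkable. No focal collection is seen. Normal vascularity on colour Doppler. Comparison was made with the previous examination. The right lobe measures 45 x 18 x 16 mm and the left lobe 42 x 15 x 14 mm.","2017-02-02",84,"UTHYD"
"SYN00002","Clinical history: Difficulty swallowing for several months.

Findings: The thyroid gland was examined with high frequency ultrasound. The thyroid is of normal size with no focal abnormality. The isthmus measures 2.5 mm. The right lobe measures 45 x 18 x 16 mm and the left lobe 42 x 15 x 14 mm. The trachea is central and the carotid arteries are patent. The visualised soft tissues of the neck are unremarkable. Comparison was made with the previous examination. The appearances are stable. No focal collection is seen.","2019-12-17",28,"UTHPY"
"SYN00003","Clinical history: Routine surveillance.

Findings: Ultrasound assessment of the thyroid gland. There are no thyroid nodules. Graded U1. Changes in the thyroid bed consistent with previous surgery. No focal collection is seen. Comparison was made with the previous examination. The appearances are stable. The trachea is central and the carotid arteries are patent. The right lobe measures 45 x 18 x 16 mm and the left lobe 42 x 15 x 14 mm. The isthmus measures 2.5 mm. The visualised soft tissues of the neck are unremarkable. Normal vascularity on colour Doppler.","2018-02-01",32,"UTHYD"
"SYN00004","Clinical history: Hypothyroidism on levothyroxine.

Findings: The thyroid gland was examined with high frequency ultrasound. The thyroid contains several nodules bilaterally. A small left parotid cyst is noted. Normal vascularity on colour Doppler. The visualised soft tissues of the neck are unremarkable. The trachea is central and the carotid arteries are patent. The appearances are stable. No focal collection is seen. Comparison was made with the previous examination. The right lobe measures 45 x 18 x 16 mm and the left lobe 42 x 15 x 14 mm. The isthmus measures 2.5 mm.","2016-08-05",69,"UNECK"
"SYN00005","Clinical history: Referred for surgery.

Findings: Ultrasound assessment of the thyroid gland. There are no thyroid nodules. The thyroid is diffusely heterogeneous in echotexture. The trachea is central and the carotid arteries are patent. No focal collection is seen. The isthmus measures 2.5 mm. The right lobe measures 45 x 18 x 16 mm and the left lobe 42 x 15 x 14 mm. The visualised soft tissues of the neck are unremarkable. Normal vascularity on colour Doppler. Comparison was made with the previous examination. The appearances are stable.","2016-09-30",40,"UTHYD"
"SYN00006","Clinical history: Difficulty swallowing for several months.

Findings: Ultrasound assessment of the thyroid gland. A single hypoechoic nodule is seen in the left lobe. The nodule has suspicious features (U4). The visualised soft tissues of the neck are unremarkable. The trachea is central and the carotid arteries are patent. The appearances are stable. The isthmus measures 2.5 mm. Comparison was made with the previous examination. Normal vascularity on colour Doppler. No focal collection is seen. The right lobe measures 45 x 18 x 16 mm and the left lobe 42 x 15 x 14 mm.","2015-11-04",42,"UNECK"
"SYN00007","Clinical history: Neck lump.

Findings: Ultrasound assessment of the thyroid gland. The thyroid contains several nodules bilaterally. The largest nodule has suspicious features (U4). The right lobe is absent in keeping with previous lobectomy. Comparison was made with the previous examination. No focal collection is seen. The isthmus measures 2.5 mm. Normal vascularity on colour Doppler. The visualised soft tissues of the neck are unremarkable. The trachea is central and the carotid arteries are patent. The appearances are stable. The right lobe measures 45 x 18 x 16 mm and the left lobe 42 x 15 x 14 mm.","2017-08-12",77,"UNECK"
"SYN00008","Clinical history: Routine surveillance.

Findings: The thyroid gland was examined with high frequency ultrasound. Thyroid nodules were not observed. Features are consistent with thyroiditis. Normal appearance of the cervical lymph nodes bilaterally. The appearances are stable. The isthmus measures 2.5 mm. Normal vascularity on colour Doppler. The visualised soft tissues of the neck are unremarkable. No focal collection is seen. Comparison was made with the previous examination. The trachea is central and the carotid arteries are patent. The right lobe measures 45 x 18 x 16 mm and the left lobe 42 x 15 x 14 mm.","2018-11-06",64,"UTHPY"
"SYN00009","Clinical history: Routine surveillance.

Findings: The thyroid gland was examined with high frequency ultrasound. A single hypoechoic nodule is seen in the left lobe. The nodule is indeterminate, graded U3. A small left parotid cyst is noted. The trachea is central and the carotid arteries are patent. The visualised soft tissues of the neck are unremarkable. The isthmus measures 2.5 mm. Comparison was made with the previous examination. The right lobe measures 45 x 18 x 16 mm and the left lobe 42 x 15 x 14 mm. No focal collection is seen. The appearances are stable. Normal vascularity on colour Doppler.","2018-06-28",40,"UNECK"
"SYN00010","Clinical history: Routine surveillance.

Findings: The thyroid gland was examined with high frequency ultrasound. No discrete nodules are seen within the thyroid. Graded U1. The thyroid gland is diffusely enlarged. The thyroid gland appears slightly enlarged. Normal appearance of the cervical lymph nodes bilaterally. A thyroglossal cyst is demonstrated in the midline. The appearances are stable. The isthmus measures 2.5 mm. The trachea is central and the carotid arteries are patent. No focal collection is seen. The visualised soft tissues of the neck are unremarkable.","2015-12-11",69,"UNECK"
"SYN00011","Clinical history: Routine surveillance.

Findings: Ultrasound assessment of the thyroid gland. Thyroid nodules were not observed. Graded U1. Comparison was made with the previous examination. The trachea is central and the carotid arteries are patent. The isthmus measures 2.5 mm. No focal collection is seen. Normal vascularity on colour Doppler. The right lobe measures 45 x 18 x 16 mm and the left lobe 42 x 15 x 14 mm. The visualised soft tissues of the neck are unremarkable. The appearances are stable.","2017-06-02",35,"UTHYD"
"SYN00012","Clinical history: Hypothyroidism on levothyroxine. Prior left lobectomy.

Findings: Ultrasound assessment of the thyroid gland. Appearances are in keeping with a multinodular goitre. The gland is heterogeneous and inflamed, in keeping with thyroiditis. The right lobe measures 45 x 18 x 16 mm and the left lobe 42 x 15 x 14 mm. The visualised soft tissues of the neck are unremarkable. The isthmus measures 2.5 mm. The appearances are stable. The trachea is central and the carotid arteries are patent. Comparison was made with the previous examination. No focal collection is seen. Normal vascularity on colour Doppler.","2015-02-13",58,"UTHPY"
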